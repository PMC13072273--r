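#' Variant table: samples x biallelic sites with diploid genotypes
#'
#' The central in-memory container of the package. Sites are rows of a
#' site data frame (contig, 1-based pos, ref, alt); genotypes are two
#' integer allele matrices (`a1`, `a2`, samples in rows, sites in
#' columns) coded 0 = reference allele, 1 = alternate allele, `NA` =
#' missing. Phase is ignored throughout. Per-site INFO annotations
#' (QD, MQ, FS, HaplotypeScore, MQRankSum, ReadPosRankSum, ...) live in
#' a numeric data frame aligned with the sites; absent annotations are
#' `NA`.
#'
#' @param sites data.frame with columns `contig` (character), `pos`
#'   (positive integer, 1-based), `ref` (character), `alt` (character).
#' @param a1,a2 integer matrices, samples x sites, entries in 0/1/`NA`.
#' @param samples character vector of unique sample identifiers.
#' @param info optional numeric data.frame of per-site annotations
#'   (one row per site).
#' @return An object of class `variant_table`.
#' @examples
#' vt <- variant_table(
#'   sites = data.frame(contig = "chr1", pos = c(10L, 20L),
#'                      ref = c("A", "C"), alt = c("G", "T")),
#'   a1 = matrix(c(0L, 0L, 1L, 0L), nrow = 2),
#'   a2 = matrix(c(0L, 1L, 1L, 0L), nrow = 2),
#'   samples = c("s1", "s2"))
#' n_sites(vt)
#' @export
variant_table <- function(sites, a1, a2, samples, info = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos <= 0L)) stop("site positions must be strictly positive")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (anyDuplicated(samples)) stop("duplicated sample ids")
  if (nrow(a1) != length(samples) || !identical(dim(a1), dim(a2)) ||
      ncol(a1) != nrow(sites))
    stop("genotype matrices must be samples x sites and congruent")
  bad <- function(m) any(!is.na(m) & (m < 0L | m > 1L))
  if (bad(a1) || bad(a2))
    stop("allele codes must be 0 (ref), 1 (alt) or NA")
  if (xor(is.na(a1), is.na(a2)) |> any())
    stop("half-missing diploid genotypes are not representable")
  if (is.null(info)) {
    info <- data.frame(matrix(numeric(0), nrow = nrow(sites), ncol = 0))
  }
  stopifnot(nrow(info) == nrow(sites))
  rownames(a1) <- rownames(a2) <- samples
  rownames(sites) <- NULL
  structure(list(sites = sites, a1 = a1, a2 = a2,
                 samples = as.character(samples), info = info),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d samples x %d biallelic sites\n",
              n_samples(x), n_sites(x)))
  cat(sprintf("  contigs: %s\n",
              paste(unique(x$sites$contig), collapse = ", ")))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  if (ncol(x$info) > 0)
    cat(sprintf("  INFO annotations: %s\n",
                paste(names(x$info), collapse = ", ")))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param vt a `variant_table`.
#' @return integer count.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @rdname n_sites
#' @export
n_samples <- function(vt) length(vt$samples)

#' Subset a variant table by site index and/or sample
#'
#' @param x a `variant_table`.
#' @param i site index (logical or integer).
#' @param j sample index or names.
#' @param ... unused.
#' @return a `variant_table`.
#' @export
`[.variant_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_sites(x))
  if (missing(j)) j <- seq_len(n_samples(x))
  variant_table(sites = x$sites[i, , drop = FALSE],
                a1 = x$a1[j, i, drop = FALSE],
                a2 = x$a2[j, i, drop = FALSE],
                samples = x$samples[if (is.character(j))
                  match(j, x$samples) else j],
                info = x$info[i, , drop = FALSE])
}

#' Alternate-allele dosage matrix
#'
#' @param vt a `variant_table`.
#' @return integer matrix (samples x sites) of 0/1/2 alt-allele counts,
#'   `NA` where the genotype is missing.
#' @export
dosage <- function(vt) vt$a1 + vt$a2

#' Per-site alternate allele frequency and call rate
#'
#' Frequencies are computed over non-missing alleles only.
#'
#' @param vt a `variant_table`.
#' @return data.frame with columns `alt_freq`, `maf`, `call_rate`,
#'   one row per site.
#' @export
site_allele_stats <- function(vt) {
  ds <- dosage(vt)
  called <- colSums(!is.na(ds))
  alt <- colSums(ds, na.rm = TRUE)
  af <- ifelse(called > 0, alt / (2 * called), NA_real_)
  data.frame(alt_freq = af,
             maf = pmin(af, 1 - af),
             call_rate = called / nrow(ds))
}

#' Read a two-column sample-to-population map
#'
#' Whitespace- or tab-separated file, one `sample population` pair per
#' line; `#` comment lines ignored.
#'
#' @param path file path.
#' @return named character vector: population label per sample id.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("sample", "population"),
                           colClasses = "character")
  if (anyDuplicated(tab$sample))
    stop("popmap assigns a sample to more than one population")
  stats::setNames(tab$population, tab$sample)
}

#' @rdname read_popmap
#' @param popmap named character vector as returned by `read_popmap`.
#' @param path output file path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(names(popmap), unname(popmap)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
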