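#' Collapse aligned mitochondrial sequences into haplotypes
#'
#' Two sequences belong to the same haplotype when they are identical
#' at every comparable column — positions where both carry a plain
#' A/C/G/T (gaps, N and ambiguity codes are not comparable).
#' Because that relation is not transitive under missing data,
#' sequences are merged greedily in input order into the earliest
#' compatible haplotype; the representative's non-comparable columns
#' are back-filled from later members, so the representative is the
#' most complete sequence the group supports.
#'
#' @param aln named character vector of equal-length aligned
#'   sequences, or a `DNAStringSet`, or a FASTA path.
#' @param popmap named character vector (sample -> population)
#'   covering every sequence.
#' @return object of class `haplotype_set`: `haplotypes` (character
#'   vector of representatives), `counts` (haplotype x population
#'   matrix), `membership` (sample -> haplotype index).
#' @export
collapse_haplotypes <- function(aln, popmap) {
  if (is.character(aln) && length(aln) == 1 && file.exists(aln))
    aln <- Biostrings::readDNAStringSet(aln)
  if (methods::is(aln, "DNAStringSet")) {
    nm <- sub("\\s.*", "", names(aln))
    aln <- stats::setNames(as.character(aln), nm)
  }
  if (length(unique(nchar(aln))) != 1)
    stop("aligned sequences must have equal length")
  missing_pm <- setdiff(names(aln), names(popmap))
  if (length(missing_pm))
    stop("samples missing from popmap: ",
         paste(missing_pm, collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  plain <- mat %in% c("A", "C", "G", "T")
  dim(plain) <- dim(mat)

  reps <- list(); rep_plain <- list()
  membership <- integer(length(aln))
  for (i in seq_along(aln)) {
    assigned <- 0L
    for (h in seq_along(reps)) {
      comp <- plain[i, ] & rep_plain[[h]]
      if (!any(comp) || all(mat[i, comp] == reps[[h]][comp])) {
        assigned <- h
        fill <- plain[i, ] & !rep_plain[[h]]
        reps[[h]][fill] <- mat[i, fill]
        rep_plain[[h]][fill] <- TRUE
        break
      }
    }
    if (assigned == 0L) {
      reps[[length(reps) + 1L]] <- mat[i, ]
      rep_plain[[length(rep_plain) + 1L]] <- plain[i, ]
      assigned <- length(reps)
    }
    membership[i] <- assigned
  }
  names(membership) <- names(aln)
  pops <- sort(unique(unname(popmap[names(aln)])))
  counts <- matrix(0L, length(reps), length(pops),
                   dimnames = list(paste0("H", seq_along(reps)), pops))
  for (i in seq_along(aln))
    counts[membership[i], popmap[names(aln)[i]]] <-
      counts[membership[i], popmap[names(aln)[i]]] + 1L
  structure(list(haplotypes = vapply(reps, paste, character(1),
                                     collapse = ""),
                 counts = counts, membership = membership),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes from %d samples\n",
              length(x$haplotypes), length(x$membership)))
  print(x$counts)
  invisible(x)
}

# Hamming distance over columns comparable in both haplotypes
hap_distance <- function(h1, h2) {
  b1 <- strsplit(h1, "")[[1]]; b2 <- strsplit(h2, "")[[1]]
  comp <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
  sum(b1[comp] != b2[comp])
}

#' Minimum spanning haplotype network
#'
#' Builds the minimum spanning network over pairwise Hamming
#' distances (mutation steps) between haplotypes: edges are added in
#' order of increasing weight, and within a weight class every edge
#' joining components that were distinct before the class is retained,
#' so all co-minimal alternatives appear.
#'
#' @param hs a `haplotype_set` with at least two haplotypes.
#' @return object of class `haplotype_network`: `edges` (data.frame
#'   `from`, `to`, `steps`), `counts`, `n_haplotypes`.
#' @export
build_haplotype_network <- function(hs) {
  n <- length(hs$haplotypes)
  if (n < 2) stop("need at least two haplotypes")
  pairs <- utils::combn(n, 2)
  w <- apply(pairs, 2, function(ij)
    hap_distance(hs$haplotypes[ij[1]], hs$haplotypes[ij[2]]))
  comp <- seq_len(n)                      # union-find by relabelling
  edges <- list(); k <- 0L
  for (wt in sort(unique(w))) {
    in_class <- which(w == wt)
    joins <- in_class[comp[pairs[1, in_class]] !=
                        comp[pairs[2, in_class]]]
    for (e in joins) {                    # keep all co-minimal edges
      k <- k + 1L
      edges[[k]] <- data.frame(from = pairs[1, e], to = pairs[2, e],
                               steps = wt)
    }
    for (e in joins) {                    # then merge components
      ci <- comp[pairs[1, e]]; cj <- comp[pairs[2, e]]
      if (ci != cj) comp[comp == cj] <- ci
    }
    if (length(unique(comp)) == 1) break
  }
  structure(list(edges = do.call(rbind, edges), counts = hs$counts,
                 n_haplotypes = n),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d haplotypes, %d edge(s)\n",
              x$n_haplotypes, nrow(x$edges)))
  print(x$edges)
  invisible(x)
}

#' Population-resolution report from a haplotype set
#'
#' For each population: the number of haplotypes private to it, the
#' number it shares with another population, and a `traceable` flag —
#' true iff every individual of the population carries a haplotype
#' found in no other population. Shared haplotypes are what defeat
#' mtDNA-based assignment.
#'
#' @param hs a `haplotype_set` over at least two populations.
#' @return data.frame with columns `population`, `n_private`,
#'   `n_shared`, `traceable`.
#' @export
resolution_report <- function(hs) {
  if (ncol(hs$counts) < 2) stop("need at least two populations")
  present <- hs$counts > 0
  n_pops_with <- rowSums(present)
  out <- data.frame(
    population = colnames(hs$counts),
    n_private = vapply(seq_len(ncol(present)), function(j)
      sum(present[, j] & n_pops_with == 1), integer(1)),
    n_shared = vapply(seq_len(ncol(present)), function(j)
      sum(present[, j] & n_pops_with > 1), integer(1)))
  out$traceable <- out$n_shared == 0
  out
}

#' Write a haplotype network as an edge-list TSV (and optional GML)
#'
#' @param net a `haplotype_network`.
#' @param path TSV output path.
#' @param gml_path optional GML output path (requires \pkg{igraph}).
#' @return `path`, invisibly.
#' @export
write_haplotype_network <- function(net, path, gml_path = NULL) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(gml_path)) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("igraph is required for GML output")
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
    igraph::E(g)$weight <- net$edges$steps
    igraph::write_graph(g, gml_path, format = "gml")
  }
  invisible(path)
}
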