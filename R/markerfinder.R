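#' Homozygous allele frequency (HAF) of an allele in a population
#'
#' The fraction of a population's genotyped individuals that are
#' homozygous for the given allele at a site. The denominator counts
#' non-missing genotypes by default; `denominator = "all"` divides by
#' every member regardless of missingness (the stricter alternative).
#'
#' @param vt a `variant_table`.
#' @param popmap named character vector (sample -> population).
#' @param pop population label.
#' @param site site index in `vt`.
#' @param allele `"ref"` or `"alt"`.
#' @param denominator `"genotyped"` (default) or `"all"`.
#' @return fraction in `[0, 1]`, or `NA` if no member is genotyped.
#' @export
compute_haf <- function(vt, popmap, pop, site, allele = c("alt", "ref"),
                        denominator = c("genotyped", "all")) {
  allele <- match.arg(allele)
  denominator <- match.arg(denominator)
  members <- vt$samples[popmap[vt$samples] == pop]
  if (length(members) == 0) stop("population has no members: ", pop)
  a1 <- vt$a1[members, site]; a2 <- vt$a2[members, site]
  called <- !is.na(a1)
  want <- if (allele == "alt") 1L else 0L
  hom <- called & a1 == want & a2 == want
  den <- if (denominator == "all") length(members) else sum(called)
  if (den == 0) return(NA_real_)
  sum(hom) / den
}

# per-population homozygote counts at every site: list of matrices
pop_hom_counts <- function(vt, popmap) {
  pops <- unique(unname(popmap[vt$samples]))
  res <- lapply(pops, function(p) {
    members <- vt$samples[popmap[vt$samples] == p]
    a1 <- vt$a1[members, , drop = FALSE]
    a2 <- vt$a2[members, , drop = FALSE]
    called <- colSums(!is.na(a1))
    hom_ref <- colSums(!is.na(a1) & a1 == 0L & a2 == 0L)
    hom_alt <- colSums(!is.na(a1) & a1 == 1L & a2 == 1L)
    list(n = length(members), called = called,
         hom_ref = hom_ref, hom_alt = hom_alt)
  })
  names(res) <- pops
  res
}

#' Scan for population-diagnostic fixed sites
#'
#' A site is diagnostic for focal population P with allele a when
#' HAF_P(a) >= t and, for every other population Q, HAF_Q(b) >= t
#' where b is the opposite allele of the biallelic site (opposite-
#' homozygote intersection). One record is emitted per (site, focal
#' population) pair. Sites where any population has zero genotyped
#' members are skipped for that comparison. Species presets for t:
#' 1.0 (eared pheasants), 0.9 (Chinese pangolins), 0.8 (Tibetan
#' macaques).
#'
#' @param vt a `variant_table`.
#' @param popmap named character vector (sample -> population), at
#'   least two populations.
#' @param t HAF threshold in (0, 1].
#' @param denominator see [compute_haf()].
#' @return data.frame (class `diagnostic_sites`) with columns `contig`,
#'   `pos`, `focal_pop`, `focal_allele`, `counter_allele`, `focal_haf`,
#'   `min_other_haf`, `gene_id` (filled by
#'   [annotate_sites_with_genes()]).
#' @export
find_diagnostic_sites <- function(vt, popmap, t = 1.0,
                                  denominator = c("genotyped", "all")) {
  denominator <- match.arg(denominator)
  if (t <= 0 || t > 1) stop("t must be in (0, 1]")
  pops <- unique(unname(popmap[vt$samples]))
  if (length(pops) < 2) stop("need at least two populations")
  hc <- pop_hom_counts(vt, popmap)
  n <- n_sites(vt)
  den <- function(p) if (denominator == "all")
    rep(hc[[p]]$n, n) else hc[[p]]$called
  haf_ref <- sapply(pops, function(p)
    ifelse(den(p) > 0, hc[[p]]$hom_ref / den(p), NA_real_))
  haf_alt <- sapply(pops, function(p)
    ifelse(den(p) > 0, hc[[p]]$hom_alt / den(p), NA_real_))
  if (n == 1) { haf_ref <- t(haf_ref); haf_alt <- t(haf_alt) }

  out <- list(); k <- 0L
  for (p in pops) {
    others <- setdiff(pops, p)
    for (al in c("ref", "alt")) {
      focal <- if (al == "ref") haf_ref[, p] else haf_alt[, p]
      other <- if (al == "ref") haf_alt[, others, drop = FALSE] else
        haf_ref[, others, drop = FALSE]
      min_other <- apply(other, 1, min)     # NA if any pop uncallable
      hit <- which(!is.na(focal) & focal >= t &
                     !is.na(min_other) & min_other >= t)
      for (s in hit) {
        k <- k + 1L
        out[[k]] <- data.frame(
          contig = vt$sites$contig[s], pos = vt$sites$pos[s],
          focal_pop = p,
          focal_allele = if (al == "ref") vt$sites$ref[s] else
            vt$sites$alt[s],
          counter_allele = if (al == "ref") vt$sites$alt[s] else
            vt$sites$ref[s],
          focal_haf = focal[s], min_other_haf = min_other[s],
          gene_id = NA_character_)
      }
    }
  }
  res <- if (k > 0) do.call(rbind, out) else
    data.frame(contig = character(0), pos = integer(0),
               focal_pop = character(0), focal_allele = character(0),
               counter_allele = character(0), focal_haf = numeric(0),
               min_other_haf = numeric(0), gene_id = character(0))
  res <- res[order(res$contig, res$pos, res$focal_pop), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("diagnostic_sites", "data.frame")
  res
}

#' Annotate diagnostic sites with genes and gate on target genes
#'
#' Each site receives the id of every gene whose exon span (longest
#' transcript) contains its position; sites inside more than one gene
#' yield duplicated, flagged records. With `targets` given, only sites
#' whose gene is in the target set are retained; `targets = NULL`
#' (no-annotation mode, for taxa without a usable GFF) passes all
#' sites through with empty gene ids.
#'
#' @param sites a `diagnostic_sites` data.frame.
#' @param genes list of `gene_model`s (may be `NULL` in no-annotation
#'   mode).
#' @param targets character vector of target gene ids, or `NULL`.
#' @return the annotated/filtered `diagnostic_sites` data.frame.
#' @export
annotate_sites_with_genes <- function(sites, genes = NULL,
                                      targets = NULL) {
  if (is.null(genes)) {
    sites$gene_id <- NA_character_
    return(sites)
  }
  hits <- lapply(seq_len(nrow(sites)), function(i) {
    inside <- vapply(genes, function(g) {
      if (g$contig != sites$contig[i]) return(FALSE)
      ex <- longest_transcript(g)
      any(sites$pos[i] >= ex$start & sites$pos[i] <= ex$end)
    }, logical(1))
    ids <- vapply(genes[inside], `[[`, character(1), "gene_id")
    if (length(ids) == 0) return(NULL)
    if (length(ids) > 1)
      warning(sprintf("site %s:%d overlaps %d genes; duplicated records",
                      sites$contig[i], sites$pos[i], length(ids)))
    out <- sites[rep(i, length(ids)), , drop = FALSE]
    out$gene_id <- ids
    out
  })
  res <- do.call(rbind, hits)
  if (is.null(res)) res <- sites[0, , drop = FALSE]
  if (!is.null(targets))
    res <- res[res$gene_id %in% targets, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("diagnostic_sites", "data.frame")
  res
}

#' Extract the amplicon window around a diagnostic site
#'
#' Cuts `flank` bases of flanking sequence on both sides of the site
#' and returns the whole window (`2 * flank + 1` bp; 1801 bp at the
#' default 900 bp flank) with the diagnostic base at its centre.
#' Sites closer than `flank` to a contig end are skipped with a
#' warning, never silently truncated.
#'
#' @param ref reference sequences (named character vector or
#'   `DNAStringSet`).
#' @param site one row of a `diagnostic_sites` data.frame.
#' @param flank flank length in bp.
#' @return object of class `amplicon_candidate` (`site`, `sequence`,
#'   `site_offset` — 0-based index of the diagnostic base, = `flank`),
#'   or `NULL` if the site is skipped.
#' @export
extract_amplicon <- function(ref, site, flank = 900) {
  contig_seq <- if (methods::is(ref, "DNAStringSet"))
    as.character(ref[[site$contig]]) else ref[[site$contig]]
  if (is.null(contig_seq)) stop("contig not in reference: ", site$contig)
  lo <- site$pos - flank; hi <- site$pos + flank
  if (lo < 1 || hi > nchar(contig_seq)) {
    warning(sprintf("site %s:%d within %d bp of contig end; skipped",
                    site$contig, site$pos, flank))
    return(NULL)
  }
  seq <- substr(contig_seq, lo, hi)
  structure(list(site = site, sequence = seq, site_offset = flank),
            class = "amplicon_candidate")
}
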