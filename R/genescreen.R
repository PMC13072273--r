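# IUPAC code for an unordered base pair
iupac_pair <- c(AA = "A", CC = "C", GG = "G", TT = "T",
                AC = "M", AG = "R", AT = "W",
                CG = "S", CT = "Y", GT = "K")

iupac_code <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  out <- iupac_pair[key]
  ifelse(is.na(out), "N", out)
}

revcomp <- function(seq_str) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_str)))
}

#' Keep genes whose longest transcript exceeds a length cutoff
#'
#' Screening for primer design starts from genes long enough to carry
#' phylogenetic signal: only genes whose longest transcript is strictly
#' longer than `min_len` (default 2000 bp) are retained.
#'
#' @param genes list of `gene_model` objects ([read_gene_models()]).
#' @param min_len minimum exon-sum length in bp (exclusive bound).
#' @return the filtered list.
#' @export
select_long_transcript_genes <- function(genes, min_len = 2000) {
  Filter(function(g) g$longest_transcript_len > min_len, genes)
}

longest_transcript <- function(gene) {
  lens <- vapply(gene$transcripts,
                 function(e) sum(e$end - e$start + 1L), integer(1))
  gene$transcripts[[which.max(lens)]]
}

#' Per-sample consensus sequence of a gene's longest transcript
#'
#' Concatenates the reference exon sequence of the longest transcript
#' (in transcript order) and substitutes the sample's variants:
#' homozygous alternate calls replace the reference base, heterozygous
#' calls become the IUPAC ambiguity code for the two alleles (the
#' bcftools `consensus -I` convention). Indel alleles are skipped with
#' a warning (SNP-only consensus). Minus-strand transcripts are
#' reverse-complemented after substitution.
#'
#' @param sample sample id present in `vt`.
#' @param gene a `gene_model`.
#' @param ref named character vector or `DNAStringSet` of reference
#'   contig sequences.
#' @param vt a `variant_table`.
#' @return consensus sequence (character scalar); its length always
#'   equals the longest transcript's exon sum.
#' @export
build_sample_consensus <- function(sample, gene, ref, vt) {
  if (!sample %in% vt$samples) stop("unknown sample: ", sample)
  contig_seq <- if (methods::is(ref, "DNAStringSet"))
    as.character(ref[[gene$contig]]) else ref[[gene$contig]]
  if (is.null(contig_seq)) stop("contig not in reference: ", gene$contig)
  ex <- longest_transcript(gene)
  if (max(ex$end) > nchar(contig_seq))
    stop("gene exons exceed contig bounds")
  bases <- unlist(lapply(seq_len(nrow(ex)), function(i)
    strsplit(substr(contig_seq, ex$start[i], ex$end[i]), "")[[1]]))
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq.int(ex$start[i], ex$end[i])))

  on_gene <- which(vt$sites$contig == gene$contig & vt$sites$pos %in% gpos)
  si <- match(sample, vt$samples)
  for (s in on_gene) {
    a1 <- vt$a1[si, s]; a2 <- vt$a2[si, s]
    if (is.na(a1)) next
    if (a1 == 0L && a2 == 0L) next
    refb <- vt$sites$ref[s]; altb <- vt$sites$alt[s]
    if (nchar(refb) != 1 || nchar(altb) != 1) {
      warning(sprintf("indel at %s:%d skipped in consensus",
                      gene$contig, vt$sites$pos[s]))
      next
    }
    k <- match(vt$sites$pos[s], gpos)
    bases[k] <- if (a1 == a2) altb else iupac_code(refb, altb)
  }
  out <- paste(bases, collapse = "")
  if (identical(gene$strand, "-")) out <- revcomp(out)
  out
}

#' Per-sample alignment of a gene across all samples
#'
#' Calls [build_sample_consensus()] for every sample of the variant
#' table; since all consensus sequences are coordinate substitutions of
#' the same transcript they are already aligned.
#'
#' @inheritParams build_sample_consensus
#' @return object of class `gene_alignment`: `gene_id` plus a named
#'   character vector `sequences` (one per sample, equal lengths).
#' @export
build_gene_alignment <- function(gene, ref, vt) {
  seqs <- vapply(vt$samples, build_sample_consensus,
                 character(1), gene = gene, ref = ref, vt = vt)
  structure(list(gene_id = gene$gene_id, sequences = seqs),
            class = "gene_alignment")
}

# pairwise p-distance with IUPAC-ambiguous positions excluded pairwise
p_distance_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  plain <- m %in% c("A", "C", "G", "T")
  dim(plain) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    comp <- plain[i, ] & plain[j, ]
    d[i, j] <- d[j, i] <- if (any(comp))
      mean(m[i, comp] != m[j, comp]) else NA_real_
  }
  d
}

#' Neighbor-joining gene tree from a gene alignment
#'
#' Builds an unrooted NJ tree (via [ape::nj()]) on the pairwise
#' p-distance of the alignment. Positions carrying an IUPAC ambiguity
#' code in either sequence of a pair are excluded from that pair's
#' denominator, so heterozygous sites never inflate the distance. The
#' result is deterministic in the input order; an all-identical
#' alignment yields a star-like tree flagged via the `"degenerate"`
#' attribute.
#'
#' @param aln a `gene_alignment` (or named character vector of aligned
#'   sequences) with at least four samples.
#' @return an [ape::phylo] tree.
#' @export
build_gene_tree <- function(aln) {
  seqs <- if (inherits(aln, "gene_alignment")) aln$sequences else aln
  if (length(seqs) < 4) stop("need at least four sequences")
  if (length(unique(nchar(seqs))) != 1) stop("sequences must be aligned")
  d <- p_distance_matrix(seqs)
  if (anyNA(d)) stop("sequence pair with no comparable positions")
  tr <- ape::nj(d)
  if (all(d[upper.tri(d)] == 0)) attr(tr, "degenerate") <- TRUE
  tr
}

# non-trivial bipartitions of an unrooted tree as canonical strings
tree_bipartitions <- function(tree, leaves) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_below))
  }
  internal <- tree$edge[tree$edge[, 2] > n_tip, 2]
  parts <- character(0)
  for (node in internal) {
    side <- sort(tips_below(node))
    other <- sort(setdiff(leaves, side))
    if (length(side) < 2 || length(other) < 2) next   # trivial split
    canon <- if (side[1] < other[1]) side else other
    parts <- c(parts, paste(canon, collapse = "\r"))
  }
  unique(parts)
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are pruned to their shared leaf set (at least four
#' leaves required), unrooted, and reduced to their sets of non-trivial
#' bipartitions; the distance is the size of the symmetric difference.
#' For binary unrooted trees on n shared leaves the maximum is
#' 2(n - 3).
#'
#' @param t1,t2 [ape::phylo] trees with overlapping leaf labels.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4)
    stop("Robinson-Foulds undefined on fewer than four shared leaves")
  p1 <- tree_bipartitions(ape::keep.tip(t1, shared), shared)
  p2 <- tree_bipartitions(ape::keep.tip(t2, shared), shared)
  length(setdiff(p1, p2)) + length(setdiff(p2, p1))
}

#' Screen genes by gene-tree concordance with a species tree
#'
#' For each gene: build the per-sample alignment and NJ gene tree, and
#' record the RF distance to the species tree together with the
#' longest-transcript length. Genes are ranked by increasing RF, ties
#' broken by longer transcript then gene id.
#'
#' @param genes list of `gene_model`s (already length-filtered).
#' @param ref reference sequences (named vector or `DNAStringSet`).
#' @param vt a `variant_table`.
#' @param species_tree an [ape::phylo] tree on the sample ids.
#' @return data.frame (class `gene_screen`) with columns `gene_id`,
#'   `transcript_len`, `rf_distance`, `rank`.
#' @export
screen_genes <- function(genes, ref, vt, species_tree) {
  recs <- lapply(genes, function(g) {
    aln <- build_gene_alignment(g, ref, vt)
    gt <- build_gene_tree(aln)
    data.frame(gene_id = g$gene_id,
               transcript_len = g$longest_transcript_len,
               rf_distance = robinson_foulds(gt, species_tree))
  })
  out <- do.call(rbind, recs)
  o <- order(out$rf_distance, -out$transcript_len, out$gene_id)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_screen", "data.frame")
  out
}

#' Pearson correlation between transcript length and RF distance
#'
#' @param records a `gene_screen` data.frame (columns `transcript_len`
#'   and `rf_distance`), at least three rows with variance in both.
#' @return list with `r` (Pearson coefficient) and `p` (two-sided
#'   t-distribution p-value).
#' @export
correlate_length_rf <- function(records) {
  if (nrow(records) < 3) stop("need at least three genes")
  if (stats::var(records$transcript_len) == 0 ||
      stats::var(records$rf_distance) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(records$transcript_len, records$rf_distance,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Select target genes with relatively small RF distance
#'
#' Either the lowest-RF quantile (default lowest quartile, order
#' statistic) or an absolute cutoff `rf <= max_rf`. Ties inside the
#' ranking are already broken by longer transcript then gene id.
#'
#' @param records a `gene_screen` data.frame.
#' @param policy `"quantile"` or `"absolute"`.
#' @param quantile_at quantile for the `"quantile"` policy.
#' @param max_rf cutoff for the `"absolute"` policy.
#' @return character vector of selected gene ids.
#' @export
select_target_genes <- function(records,
                                policy = c("quantile", "absolute"),
                                quantile_at = 0.25, max_rf = 0) {
  policy <- match.arg(policy)
  cut <- switch(policy,
                quantile = unname(stats::quantile(records$rf_distance,
                                                  quantile_at, type = 1)),
                absolute = max_rf)
  records$gene_id[records$rf_distance <= cut]
}
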