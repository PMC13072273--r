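#' Run the complete traceability pipeline
#'
#' Executes the marker-design chain end to end: variant hard and
#' frequency filtering, population-structure summaries (kinship, PCA),
#' gene screening by gene-tree/species-tree concordance (when an
#' annotation is supplied), the HAF scan for population-diagnostic
#' sites, gene gating, amplicon extraction and primer design. The
#' result is a per-population marker table shaped like a primer
#' report: Pop, Gene, Mutation ("ref-alt" from the focal population's
#' perspective), Left Primer, Right Primer.
#'
#' Within each population, candidate markers are ranked
#' deterministically: sites in target genes first, then larger
#' `min_other_haf`, then smaller position; primer design is attempted
#' in that order until `markers_per_pop` primer-bearing markers are
#' found.
#'
#' @param vcf path to the multi-sample VCF (or a `variant_table`).
#' @param popmap path to a two-column popmap file (or a named vector).
#' @param ref path to the reference FASTA (or named sequences).
#' @param gff optional path to the GFF3 annotation (or a list of
#'   `gene_model`s); `NULL` runs the no-annotation mode.
#' @param species_tree optional [ape::phylo] species tree on the
#'   sample ids; by default computed by neighbor joining on the
#'   concatenated screened transcripts.
#' @param haf_t HAF threshold (presets: 1.0 pheasant, 0.9 pangolin,
#'   0.8 macaque).
#' @param flank amplicon flank in bp.
#' @param pc a [primer_constraints()] object.
#' @param markers_per_pop primer-bearing markers sought per population.
#' @param min_transcript_len gene length cutoff (bp, exclusive).
#' @param target_quantile RF quantile defining target genes.
#' @param apply_filters run the hard/frequency filters first.
#' @return object of class `trace_panel`: the marker `table`, the full
#'   `sites` scan, `amplicons`, `primers`, `gene_screen`, `kinship`,
#'   `pca`, and the filtered `variant_table`.
#' @export
run_traceability_pipeline <- function(vcf, popmap, ref, gff = NULL,
                                      species_tree = NULL,
                                      haf_t = 1.0, flank = 900,
                                      pc = primer_constraints(),
                                      markers_per_pop = 1,
                                      min_transcript_len = 2000,
                                      target_quantile = 0.25,
                                      apply_filters = TRUE) {
  vt <- if (inherits(vcf, "variant_table")) vcf else
    read_variant_table(vcf)
  pm <- if (is.character(popmap) && length(popmap) == 1 &&
            file.exists(popmap)) read_popmap(popmap) else popmap
  refseq <- if (is.character(ref) && length(ref) == 1 &&
                file.exists(ref))
    Biostrings::readDNAStringSet(ref) else ref
  if (methods::is(refseq, "DNAStringSet"))
    names(refseq) <- sub("\\s.*", "", names(refseq))
  genes <- if (is.null(gff)) NULL else
    if (is.character(gff)) read_gene_models(gff) else gff

  halt <- function(stage) stop(sprintf(
    "pipeline halted: stage '%s' produced empty output", stage),
    call. = FALSE)

  if (apply_filters) {
    th <- hard_filter_thresholds()
    vt <- apply_hard_filters(vt, th)
    if (n_sites(vt) == 0) halt("hard_filters")
    vt <- apply_frequency_filters(vt, th)
    if (n_sites(vt) == 0) halt("frequency_filters")
  }

  kin <- compute_ibs_kinship(vt)
  pca <- compute_pca(vt, n_components = min(3, n_samples(vt) - 1))

  screen <- NULL; targets <- NULL
  if (!is.null(genes)) {
    long_genes <- select_long_transcript_genes(genes, min_transcript_len)
    if (length(long_genes) == 0) halt("long_transcript_selection")
    if (is.null(species_tree)) {
      concat <- vapply(vt$samples, function(s) paste(
        vapply(long_genes, function(g)
          build_sample_consensus(s, g, refseq, vt), character(1)),
        collapse = ""), character(1))
      species_tree <- build_gene_tree(concat)
    }
    screen <- screen_genes(long_genes, refseq, vt, species_tree)
    targets <- select_target_genes(screen, quantile_at = target_quantile)
    if (length(targets) == 0) halt("target_gene_selection")
  }

  sites <- find_diagnostic_sites(vt, pm, t = haf_t)
  if (nrow(sites) == 0) halt("find_diagnostic_sites")
  gated <- annotate_sites_with_genes(sites, genes, targets)
  if (nrow(gated) == 0) halt("gene_gating")

  # deterministic per-population ranking: target-gene sites first,
  # then max min_other_haf, then smallest position
  rank_key <- order(gated$focal_pop, is.na(gated$gene_id),
                    -gated$min_other_haf, gated$pos)
  gated <- gated[rank_key, , drop = FALSE]

  rows <- list(); amps <- list(); prims <- list(); k <- 0L
  for (p in unique(gated$focal_pop)) {
    found <- 0L
    cand <- gated[gated$focal_pop == p, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      if (found >= markers_per_pop) break
      amp <- withCallingHandlers(
        extract_amplicon(refseq, cand[i, ], flank = flank),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(amp)) next
      pp <- design_primer_pairs(amp, pc)
      if (nrow(pp) == 0) next
      found <- found + 1L; k <- k + 1L
      ref_allele <- substr(amp$sequence, amp$site_offset + 1,
                           amp$site_offset + 1)
      mut <- paste0(cand$focal_allele[i], "-", cand$counter_allele[i])
      rows[[k]] <- data.frame(
        Pop = p,
        Gene = ifelse(is.na(cand$gene_id[i]), "", cand$gene_id[i]),
        Mutation = mut,
        `Left Primer` = pp$left_seq[1], `Right Primer` = pp$right_seq[1],
        contig = cand$contig[i], pos = cand$pos[i],
        check.names = FALSE)
      amps[[k]] <- amp; prims[[k]] <- pp
    }
    if (found == 0) halt(sprintf("primer_design[%s]", p))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, sites = sites, gated_sites = gated,
                 amplicons = amps, primers = prims,
                 gene_screen = screen, targets = targets,
                 kinship = kin, pca = pca, variant_table = vt,
                 haf_t = haf_t, flank = flank),
            class = "trace_panel")
}

#' @export
print.trace_panel <- function(x, ...) {
  cat(sprintf("trace_panel: %d marker(s) across %d population(s), HAF >= %g\n",
              nrow(x$table), length(unique(x$table$Pop)), x$haf_t))
  print(x$table[, c("Pop", "Gene", "Mutation", "Left Primer",
                    "Right Primer")])
  invisible(x)
}

#' @export
summary.trace_panel <- function(object, ...) {
  cat("Traceability panel summary\n")
  cat(sprintf("  filtered sites: %d, samples: %d\n",
              n_sites(object$variant_table),
              n_samples(object$variant_table)))
  cat(sprintf("  diagnostic site records: %d (gated: %d)\n",
              nrow(object$sites), nrow(object$gated_sites)))
  if (!is.null(object$gene_screen))
    cat(sprintf("  genes screened: %d, target genes: %d\n",
                nrow(object$gene_screen), length(object$targets)))
  cat(sprintf("  PCA variance fractions: %s\n",
              paste(sprintf("%.1f%%",
                            100 * object$pca$variance_fraction),
                    collapse = ", ")))
  print(object)
  invisible(object)
}

#' Write the marker table of a panel as TSV
#' @param panel a `trace_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(panel, path) {
  utils::write.table(panel$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write diagnostic sites as a BED file (0-based half-open)
#' @param sites a `diagnostic_sites` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$contig, sites$pos - 1L, sites$pos,
                    paste0(sites$focal_pop, "_", sites$focal_allele))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
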