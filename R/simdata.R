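#' Configuration for the synthetic traceability data generator
#'
#' Defines the planted study conditions: three populations of eight
#' samples by default, a single contig carrying long (> 2000 bp
#' longest transcript) and short genes, 2000 background SNPs with
#' hierarchical population structure, ten fully fixed diagnostic
#' sites planted per population inside long-gene exons, and a
#' mitochondrial alignment with configurable haplotype sharing.
#'
#' Background sites are guaranteed non-diagnostic at HAF t = 1.0 by
#' construction: every background site carries at least one called
#' heterozygote, which breaks both focal fixation and opposite
#' fixation for every population. Missingness is applied to
#' background sites only, so planted sites meet their stated HAF
#' exactly.
#'
#' @param seed integer seed; all generator output is bit-reproducible
#'   from `(seed, cfg)`.
#' @param n_pops number of populations.
#' @param samples_per_pop samples per population.
#' @param contig_length reference contig length (bp).
#' @param n_long_genes,n_short_genes gene counts above/below the
#'   2000 bp longest-transcript cutoff.
#' @param long_transcript_len,short_transcript_len exon-sum lengths
#'   (bp) of the longest transcript of each gene class.
#' @param n_background_sites background SNP count.
#' @param n_planted_per_pop planted diagnostic sites per population.
#' @param planted_focal_haf focal-population HAF of planted sites.
#' @param background_freq_range ancestral allele-frequency range for
#'   background sites.
#' @param fst per-split drift intensity of the hierarchical
#'   Balding-Nichols frequency model.
#' @param missing_rate genotype missing rate (background sites only).
#' @param mt_len mitochondrial alignment length (bp).
#' @param mt_haps_per_pop mitochondrial haplotypes per population.
#' @param mt_shared_pairs number of adjacent population pairs that
#'   share one mitochondrial haplotype.
#' @param flank amplicon flank (bp); planted sites keep at least this
#'   distance from contig ends.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 20260101,
                       n_pops = 3, samples_per_pop = 8,
                       contig_length = 60000,
                       n_long_genes = 4, n_short_genes = 2,
                       long_transcript_len = 2400,
                       short_transcript_len = 1200,
                       n_background_sites = 2000,
                       n_planted_per_pop = 10,
                       planted_focal_haf = 1.0,
                       background_freq_range = c(0.1, 0.9),
                       fst = 0.1, missing_rate = 0.02,
                       mt_len = 16500, mt_haps_per_pop = 2,
                       mt_shared_pairs = 0, flank = 900) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pops >= 2, cfg$samples_per_pop >= 1,
            cfg$planted_focal_haf > 0, cfg$planted_focal_haf <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$mt_len >= 100,
            cfg$mt_shared_pairs <= cfg$n_pops - 1)
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# exon layout for one transcript: total exon sum `len` split into
# `n_ex` exons separated by `intron` bp, starting at `start`
make_exons <- function(start, len, n_ex = 3, intron = 200) {
  sizes <- rep(len %/% n_ex, n_ex)
  sizes[n_ex] <- sizes[n_ex] + len %% n_ex
  s <- start; rows <- list()
  for (i in seq_len(n_ex)) {
    rows[[i]] <- data.frame(start = as.integer(s),
                            end = as.integer(s + sizes[i] - 1L))
    s <- s + sizes[i] + intron
  }
  do.call(rbind, rows)
}

#' Simulate a reference contig and gene annotation
#'
#' Generates a random reference sequence and a set of gene models:
#' `n_long_genes` whose longest transcript exceeds 2000 bp (each with
#' a shorter secondary transcript, to exercise longest-transcript
#' selection) and `n_short_genes` at or below the cutoff. Genes are
#' laid out non-overlapping, at least `flank` bases from the contig
#' ends.
#'
#' @param cfg a [sim_config()].
#' @return list with `ref` (named character vector, one contig) and
#'   `genes` (list of `gene_model`).
#' @export
simulate_reference_and_annotation <- function(cfg) {
  set.seed(cfg$seed)
  n_genes <- cfg$n_long_genes + cfg$n_short_genes
  span_long <- cfg$long_transcript_len + 2 * 200
  span_short <- cfg$short_transcript_len + 200
  gap <- 600
  need <- 2 * cfg$flank + cfg$n_long_genes * (span_long + gap) +
    cfg$n_short_genes * (span_short + gap)
  if (need > cfg$contig_length)
    stop("infeasible packing: contig too short for the gene layout")
  genes <- list()
  cursor <- cfg$flank + 1L
  for (g in seq_len(n_genes)) {
    long <- g <= cfg$n_long_genes
    gid <- sprintf("gene%02d", g)
    tlen <- if (long) cfg$long_transcript_len else
      cfg$short_transcript_len
    ex1 <- make_exons(cursor, tlen, n_ex = if (long) 3 else 2)
    txs <- stats::setNames(list(ex1), paste0(gid, ".t1"))
    if (long) {   # secondary, shorter transcript: first two exons
      txs[[paste0(gid, ".t2")]] <- ex1[1:2, , drop = FALSE]
    }
    lens <- vapply(txs, function(e) sum(e$end - e$start + 1L),
                   integer(1))
    genes[[gid]] <- structure(
      list(gene_id = gid, contig = "chr1",
           strand = if (g %% 5 == 0) "-" else "+",
           transcripts = txs,
           longest_transcript_len = max(lens)),
      class = "gene_model")
    cursor <- max(ex1$end) + gap
  }
  ref <- stats::setNames(rand_dna(cfg$contig_length), "chr1")
  list(ref = ref, genes = unname(genes))
}

# Balding-Nichols draw: beta around p with drift intensity f
bn_draw <- function(p, f, n = 1) {
  a <- p * (1 - f) / f; b <- (1 - p) * (1 - f) / f
  stats::rbeta(n, a, b)
}

#' Simulate population genotypes with planted diagnostic sites
#'
#' Background sites get per-population alternate-allele frequencies
#' from a two-level hierarchical Balding-Nichols model over a
#' balanced population tree (two clades, then populations), giving
#' PCA, kinship and D statistics realistic signal; genotypes are
#' binomial draws from those frequencies. Planted sites are fully
#' opposite-fixed: the focal population is homozygous alternate in a
#' `planted_focal_haf` fraction of members (heterozygous otherwise)
#' and every other population is homozygous reference. Planted
#' positions fall inside long-gene exons, round-robin across genes,
#' at least `flank` bases from contig ends.
#'
#' Optional gene flow: `introgression = list(from, to, rate)` makes
#' population `to` inherit population `from`'s allele frequency at a
#' `rate` fraction of background sites (drawn per site), which a
#' D-statistic trio containing both detects as |Z| > 3.
#'
#' @param cfg a [sim_config()].
#' @param ref,genes output of [simulate_reference_and_annotation()].
#' @param introgression optional list(from, to, rate).
#' @return list with `vt` (a `variant_table`), `popmap` (named
#'   character vector), and `truth` (data.frame of planted
#'   `contig`, `pos`, `focal_pop`, `focal_allele`).
#' @export
simulate_population_genotypes <- function(cfg, ref, genes,
                                          introgression = NULL) {
  set.seed(cfg$seed + 1L)
  pops <- paste0("pop", LETTERS[seq_len(cfg$n_pops)])
  samples <- unlist(lapply(pops, function(p)
    sprintf("%s_s%02d", p, seq_len(cfg$samples_per_pop))))
  popmap <- stats::setNames(rep(pops, each = cfg$samples_per_pop),
                            samples)
  n_samp <- length(samples)
  contig <- names(ref)[1]
  ref_chars <- strsplit(unname(ref[1]), "")[[1]]

  # planted positions: round-robin over long-gene exon positions
  long_genes <- Filter(function(g) g$longest_transcript_len > 2000,
                       genes)
  exon_pos <- lapply(long_genes, function(g) {
    ex <- longest_transcript(g)
    unlist(Map(seq.int, ex$start, ex$end))
  })
  n_planted <- cfg$n_pops * cfg$n_planted_per_pop
  planted_pos <- integer(0); gi <- 0L
  for (k in seq_len(n_planted)) {
    gi <- gi %% length(exon_pos) + 1L
    avail <- setdiff(exon_pos[[gi]], planted_pos)
    avail <- avail[avail > cfg$flank &
                     avail <= cfg$contig_length - cfg$flank]
    if (length(avail) == 0) stop("no exon positions left for planting")
    planted_pos <- c(planted_pos, sample(avail, 1))
  }
  planted_pop <- rep(pops, each = cfg$n_planted_per_pop)

  bg_avail <- setdiff(seq_len(cfg$contig_length), planted_pos)
  bg_pos <- sort(sample(bg_avail, cfg$n_background_sites))

  all_pos <- c(bg_pos, planted_pos)
  ord <- order(all_pos)
  is_planted <- c(rep(FALSE, length(bg_pos)),
                  rep(TRUE, length(planted_pos)))
  site_pop <- c(rep(NA_character_, length(bg_pos)), planted_pop)

  n_sites_tot <- length(all_pos)
  a1 <- matrix(NA_integer_, n_samp, n_sites_tot,
               dimnames = list(samples, NULL))
  a2 <- a1

  # hierarchical frequencies for background sites: the first n-1
  # populations fall into two ingroup clades; the last population is
  # basal (drawn straight from the ancestral frequency), giving D and
  # f4 analyses a genuine outgroup to polarize against
  n_in <- max(cfg$n_pops - 1L, 2L)
  clade_of <- rep(1:2, length.out = cfg$n_pops)
  basal <- if (cfg$n_pops >= 3) cfg$n_pops else integer(0)
  for (s in which(!is_planted)) {
    p0 <- stats::runif(1, cfg$background_freq_range[1],
                       cfg$background_freq_range[2])
    p_clade <- bn_draw(p0, cfg$fst, 2)
    p_pop <- vapply(seq_len(cfg$n_pops), function(i)
      if (i %in% basal) bn_draw(p0, cfg$fst / 2) else
        bn_draw(p_clade[clade_of[i]], cfg$fst), numeric(1))
    if (!is.null(introgression) &&
        stats::runif(1) < introgression$rate) {
      p_pop[match(introgression$to, pops)] <-
        p_pop[match(introgression$from, pops)]
    }
    for (i in seq_len(cfg$n_pops)) {
      rows <- which(popmap == pops[i])
      g1 <- stats::rbinom(length(rows), 1, p_pop[i])
      g2 <- stats::rbinom(length(rows), 1, p_pop[i])
      a1[rows, s] <- pmin(g1, g2); a2[rows, s] <- pmax(g1, g2)
    }
    # missingness (background only), then force >= 1 called het
    miss <- stats::runif(n_samp) < cfg$missing_rate
    miss[1] <- FALSE
    a1[miss, s] <- NA_integer_; a2[miss, s] <- NA_integer_
    called <- which(!miss)
    if (!any(a1[called, s] != a2[called, s])) {
      a1[called[1], s] <- 0L; a2[called[1], s] <- 1L
    }
  }

  # planted sites: focal pop hom-alt (het for the remainder),
  # all other pops hom-ref; no missingness
  for (k in seq_along(planted_pos)) {
    s <- length(bg_pos) + k
    focal_rows <- which(popmap == planted_pop[k])
    n_hom <- round(cfg$planted_focal_haf * length(focal_rows))
    hom <- focal_rows[seq_len(n_hom)]
    het <- setdiff(focal_rows, hom)
    a1[, s] <- 0L; a2[, s] <- 0L
    a1[hom, s] <- 1L; a2[hom, s] <- 1L
    a2[het, s] <- 1L
  }

  a1 <- a1[, ord, drop = FALSE]; a2 <- a2[, ord, drop = FALSE]
  pos_sorted <- all_pos[ord]
  refb <- ref_chars[pos_sorted]
  altb <- vapply(refb, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  n_st <- length(pos_sorted)
  info <- data.frame(
    QD = stats::runif(n_st, 10, 30),
    MQ = stats::runif(n_st, 50, 60),
    FS = stats::runif(n_st, 0, 10),
    MQRankSum = stats::runif(n_st, -2, 2),
    ReadPosRankSum = stats::runif(n_st, -2, 2))
  vt <- variant_table(
    sites = data.frame(contig = contig, pos = pos_sorted,
                       ref = refb, alt = unname(altb)),
    a1 = a1, a2 = a2, samples = samples, info = info)
  truth <- data.frame(contig = rep(contig, length(planted_pos)),
                      pos = planted_pos,
                      focal_pop = planted_pop,
                      focal_allele = unname(altb[match(planted_pos,
                                                       pos_sorted)]))
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(vt = vt, popmap = popmap, truth = truth)
}

#' Simulate an aligned mitochondrial haplotype set
#'
#' Builds a base mitochondrial sequence and, per population,
#' `mt_haps_per_pop` distinct haplotypes (random substitutions on the
#' base). For the first `mt_shared_pairs` adjacent population pairs,
#' one haplotype of the second population's pool is replaced by one
#' from the first's, planting the haplotype sharing that defeats
#' mtDNA traceability. Samples draw haplotypes from their
#' population's pool cyclically, so every pool member is carried.
#'
#' @param cfg a [sim_config()].
#' @param popmap named character vector (sample -> population).
#' @return list with `aln` (named character vector of aligned
#'   sequences) and `shared_pairs` (data.frame of planted sharing).
#' @export
simulate_mt_haplotypes <- function(cfg, popmap) {
  set.seed(cfg$seed + 2L)
  pops <- unique(unname(popmap))
  base <- strsplit(rand_dna(cfg$mt_len), "")[[1]]
  mutate <- function(seq_chars, n_mut) {
    pos <- sample(length(seq_chars), n_mut)
    seq_chars[pos] <- vapply(seq_chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    seq_chars
  }
  pools <- list()
  for (p in pops) {
    pools[[p]] <- replicate(cfg$mt_haps_per_pop,
                            paste(mutate(base, sample(5:15, 1)),
                                  collapse = ""))
    while (anyDuplicated(unlist(pools)) > 0)
      pools[[p]][1] <- paste(mutate(base, sample(5:15, 1)),
                             collapse = "")
  }
  shared <- list()
  if (cfg$mt_shared_pairs > 0) {
    for (k in seq_len(cfg$mt_shared_pairs)) {
      p_from <- pops[k]; p_to <- pops[k + 1]
      pools[[p_to]][1] <- pools[[p_from]][1]
      shared[[k]] <- data.frame(pop1 = p_from, pop2 = p_to)
    }
  }
  aln <- character(0)
  for (p in pops) {
    members <- names(popmap)[popmap == p]
    idx <- rep(seq_len(cfg$mt_haps_per_pop),
               length.out = length(members))
    aln[members] <- pools[[p]][idx]
  }
  list(aln = aln,
       shared_pairs = if (length(shared)) do.call(rbind, shared) else
         data.frame(pop1 = character(0), pop2 = character(0)))
}

#' Generate a complete synthetic traceability data set
#'
#' Runs the three generators in order and optionally writes the
#' standard file formats (FASTA reference, GFF3 annotation, VCF,
#' popmap, mitochondrial FASTA alignment, truth TSV) to a directory.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @param introgression passed to
#'   [simulate_population_genotypes()].
#' @return list with `ref`, `genes`, `vt`, `popmap`, `truth`, `mt`
#'   and, when `dir` is given, `paths`.
#' @export
simulate_traceability_data <- function(cfg = sim_config(), dir = NULL,
                                       introgression = NULL) {
  ra <- simulate_reference_and_annotation(cfg)
  pg <- simulate_population_genotypes(cfg, ra$ref, ra$genes,
                                      introgression)
  mt <- simulate_mt_haplotypes(cfg, pg$popmap)
  out <- list(ref = ra$ref, genes = ra$genes, vt = pg$vt,
              popmap = pg$popmap, truth = pg$truth, mt = mt)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      ref = file.path(dir, "reference.fa"),
      gff = file.path(dir, "genes.gff3"),
      vcf = file.path(dir, "variants.vcf"),
      popmap = file.path(dir, "popmap.txt"),
      mt = file.path(dir, "mt_alignment.fa"),
      truth = file.path(dir, "truth_sites.tsv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(out$ref), paths$ref)
    write_gene_models_gff3(out$genes, paths$gff)
    write_variant_table(out$vt, paths$vcf)
    write_popmap(out$popmap, paths$popmap)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(out$mt$aln), paths$mt)
    utils::write.table(out$truth, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Write gene models as a GFF3 file
#'
#' @param genes list of `gene_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- range(unlist(lapply(g$transcripts, function(e)
      c(e$start, e$end))))
    line <- function(type, st, en, id, parent = NULL) {
      attrs <- paste0("ID=", id,
                      if (!is.null(parent)) paste0(";Parent=", parent))
      paste(g$contig, "snptrace", type, st, en, ".", g$strand, ".",
            attrs, sep = "\t")
    }
    writeLines(line("gene", span[1], span[2], g$gene_id), con)
    for (tid in names(g$transcripts)) {
      ex <- g$transcripts[[tid]]
      writeLines(line("mRNA", min(ex$start), max(ex$end), tid,
                      g$gene_id), con)
      for (i in seq_len(nrow(ex)))
        writeLines(line("exon", ex$start[i], ex$end[i],
                        paste0(tid, ".e", i), tid), con)
    }
  }
  invisible(path)
}
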