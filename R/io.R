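#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into a [variant_table()].
#' Only the GT field of the genotype columns is used; phase separators
#' (`|`) are treated like `/`. Multiallelic records are handled per
#' `multiallelic`: `"split"` (default) emits one biallelic record per
#' alternate allele at the same position, recoding genotype alleles as
#' 0 (reference), 1 (the focal alternate) and missing for any other
#' alternate; `"drop"` removes multiallelic records.
#'
#' The standard GATK hard-filter annotations (QD, MQ, FS,
#' HaplotypeScore, MQRankSum, ReadPosRankSum) are pulled from INFO when
#' present; absent annotations are `NA`.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param multiallelic `"split"` or `"drop"`.
#' @return a `variant_table`.
#' @export
read_variant_table <- function(path, multiallelic = c("split", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single record
  if (nrow(fix) == 0) stop("VCF contains no variant records")
  fmt <- if (ncol(v@gt) >= 1) v@gt[, 1] else stop("VCF has no genotype columns")
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("every record must carry a GT field")
  samples <- colnames(v@gt)[-1]
  if (anyDuplicated(samples)) stop("duplicated sample ids in VCF header")

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  # allele index pair per record x sample; NA for ./."
  split_gt <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    parts <- strsplit(g, "[/|]")
    a1 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 1) p[1] else NA_character_, character(1))))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else p[1], character(1))))
    list(a1 = a1, a2 = a2)
  }

  info_keys <- c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
                 "ReadPosRankSum")
  info_raw <- lapply(info_keys, function(k)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = k))))
  names(info_raw) <- info_keys
  keep_keys <- info_keys[vapply(info_raw, function(x) any(!is.na(x)),
                                logical(1))]

  alt_lists <- strsplit(fix[, "ALT"], ",")
  n_alt <- lengths(alt_lists)
  rec_use <- if (multiallelic == "drop") which(n_alt == 1) else
    which(n_alt >= 1)

  out_sites <- list(); out_a1 <- list(); out_a2 <- list(); out_info <- list()
  k <- 0L
  for (r in rec_use) {
    g <- split_gt(gt[r, ])
    for (ai in seq_len(n_alt[r])) {
      if (multiallelic == "drop" && n_alt[r] > 1) next
      # recode against focal alt `ai`: other alts become missing
      rc <- function(a) ifelse(is.na(a), NA_integer_,
                        ifelse(a == 0L, 0L,
                        ifelse(a == ai, 1L, NA_integer_)))
      b1 <- rc(g$a1); b2 <- rc(g$a2)
      half <- xor(is.na(b1), is.na(b2))
      b1[half] <- NA_integer_; b2[half] <- NA_integer_
      k <- k + 1L
      out_sites[[k]] <- data.frame(
        contig = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alt_lists[[r]][ai])
      out_a1[[k]] <- b1; out_a2[[k]] <- b2
      out_info[[k]] <- vapply(keep_keys, function(kk) info_raw[[kk]][r],
                              numeric(1))
    }
  }
  if (k == 0L) stop("no biallelic records retained from VCF")
  info <- as.data.frame(do.call(rbind, out_info))
  if (length(keep_keys) == 0) info <- data.frame(row.names = seq_len(k))
  variant_table(sites = do.call(rbind, out_sites),
                a1 = do.call(cbind, out_a1),
                a2 = do.call(cbind, out_a2),
                samples = samples, info = info)
}

#' Write a variant table as a minimal VCF v4.2 file
#'
#' Emits plain-text VCF with GT-only genotype columns and the table's
#' numeric INFO annotations. Genotypes are written unphased.
#'
#' @param vt a `variant_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=snptrace_%s",
                       as.character(utils::packageVersion("snptrace"))),
               vapply(names(vt$info), function(k) sprintf(
                 "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                 k, k), character(1)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       vt$samples), collapse = "\t")), con)
  gt_str <- matrix(".", n_samples(vt), n_sites(vt))
  ok <- !is.na(vt$a1)
  gt_str[ok] <- paste0(vt$a1[ok], "/", vt$a2[ok])
  gt_str[!ok] <- "./."
  for (i in seq_len(n_sites(vt))) {
    info_i <- if (ncol(vt$info) > 0) {
      vals <- unlist(vt$info[i, , drop = TRUE])
      keep <- !is.na(vals)
      if (any(keep)) paste(paste0(names(vt$info)[keep], "=",
                                  format(vals[keep], trim = TRUE)),
                           collapse = ";") else "."
    } else "."
    writeLines(paste(c(vt$sites$contig[i], vt$sites$pos[i], ".",
                       vt$sites$ref[i], vt$sites$alt[i], ".", "PASS",
                       info_i, "GT", gt_str[, i]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Variant quality and frequency filter thresholds
#'
#' Bundles the GATK-style hard-filter cutoffs and the vcftools-style
#' frequency cutoffs used to clean a raw variant table. Defaults are
#' the standard short-variant hard-filtering recipe: a site is removed
#' if QD < 2.0, MQ < 40.0, FS > 60.0, HaplotypeScore > 13.0,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.0 (strict inequalities, as
#' printed), then sites with minor allele frequency below 0.05 or call
#' rate below 0.9 are dropped (inclusive bounds, vcftools semantics).
#'
#' @param qd_min,mq_min,fs_max,haplotype_score_max,mq_rank_sum_min,read_pos_rank_sum_min
#'   hard-filter cutoffs on the INFO annotations of the same names.
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @param call_rate_min minimum fraction of genotyped samples, in `[0, 1]`.
#' @return object of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0,
                                   fs_max = 60.0,
                                   haplotype_score_max = 13.0,
                                   mq_rank_sum_min = -12.5,
                                   read_pos_rank_sum_min = -8.0,
                                   maf_min = 0.05, call_rate_min = 0.9) {
  th <- list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
             haplotype_score_max = haplotype_score_max,
             mq_rank_sum_min = mq_rank_sum_min,
             read_pos_rank_sum_min = read_pos_rank_sum_min,
             maf_min = maf_min, call_rate_min = call_rate_min)
  if (!all(vapply(th, is.finite, logical(1))))
    stop("all thresholds must be finite")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (call_rate_min < 0 || call_rate_min > 1)
    stop("call_rate_min must be in [0, 1]")
  structure(th, class = "hard_filter_thresholds")
}

#' Apply GATK-style hard filters to a variant table
#'
#' A site is removed iff any of the threshold inequalities holds for an
#' annotation that is present; absent (`NA`) annotations pass their
#' sub-filter, mirroring GATK VariantFiltration. Site order is
#' preserved. The filter is a per-site predicate, so it is idempotent
#' and commutes with [apply_frequency_filters()].
#'
#' @param vt a `variant_table`.
#' @param th a [hard_filter_thresholds()] object.
#' @return the filtered `variant_table`.
#' @export
apply_hard_filters <- function(vt, th = hard_filter_thresholds()) {
  stopifnot(inherits(th, "hard_filter_thresholds"))
  n <- n_sites(vt)
  ann <- function(key) if (key %in% names(vt$info))
    vt$info[[key]] else rep(NA_real_, n)
  fails <- function(x, bad) !is.na(x) & bad(x)
  drop <- fails(ann("QD"), function(x) x < th$qd_min) |
    fails(ann("MQ"), function(x) x < th$mq_min) |
    fails(ann("FS"), function(x) x > th$fs_max) |
    fails(ann("HaplotypeScore"), function(x) x > th$haplotype_score_max) |
    fails(ann("MQRankSum"), function(x) x < th$mq_rank_sum_min) |
    fails(ann("ReadPosRankSum"), function(x) x < th$read_pos_rank_sum_min)
  vt[!drop, ]
}

#' Apply minor-allele-frequency and call-rate filters
#'
#' Retains sites with MAF >= `maf_min` (computed over non-missing
#' alleles) and call rate >= `call_rate_min`; both bounds inclusive.
#' Sites at which every genotype is missing are removed with a warning.
#'
#' @inheritParams apply_hard_filters
#' @return the filtered `variant_table`.
#' @export
apply_frequency_filters <- function(vt, th = hard_filter_thresholds()) {
  stopifnot(inherits(th, "hard_filter_thresholds"))
  st <- site_allele_stats(vt)
  all_missing <- st$call_rate == 0
  if (any(all_missing))
    warning(sprintf("%d site(s) with all genotypes missing removed",
                    sum(all_missing)))
  keep <- !all_missing & st$maf >= th$maf_min &
    st$call_rate >= th$call_rate_min
  vt[keep, ]
}

#' Gene models read from a GFF3 annotation
#'
#' Parses gene/mRNA(transcript)/exon features (via \pkg{rtracklayer})
#' into one record per gene: transcript exon structures and the length
#' of the longest transcript (sum of its exon lengths, 1-based closed
#' intervals). Exons whose Parent transcript cannot be resolved are
#' skipped with a warning.
#'
#' @param path GFF3 file path.
#' @return list of `gene_model` objects (fields `gene_id`, `contig`,
#'   `strand`, `transcripts` — a named list of exon data frames with
#'   `start`/`end` — and `longest_transcript_len`).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- tolower(as.character(gff$type))
  if (any(S4Vectors::elementNROWS(gff$Parent) > 1))
    warning("multi-parent features: first parent used")
  parent <- vapply(as.list(gff$Parent), function(p)
    if (length(p) >= 1) p[[1]] else NA_character_, character(1))
  id <- gff$ID
  is_gene <- typ == "gene"
  is_tx <- typ %in% c("mrna", "transcript")
  is_exon <- typ == "exon"
  if (any(GenomicRanges::start(gff) > GenomicRanges::end(gff)))
    stop("malformed coordinates: end < start")
  tx2gene <- stats::setNames(parent[is_tx], id[is_tx])
  genes <- list()
  for (gi in which(is_gene)) {
    gid <- id[gi]
    tx_ids <- id[is_tx][tx2gene == gid]
    txs <- list()
    for (tid in tx_ids) {
      ex <- which(is_exon & parent == tid)
      if (length(ex) == 0) next
      o <- order(GenomicRanges::start(gff)[ex])
      txs[[tid]] <- data.frame(start = GenomicRanges::start(gff)[ex][o],
                               end = GenomicRanges::end(gff)[ex][o])
    }
    orphans <- sum(is_exon & !(parent %in% id[is_tx]) & parent == gid)
    if (orphans > 0)
      warning(sprintf("gene %s: %d exon(s) without resolvable transcript parent skipped",
                      gid, orphans))
    lens <- vapply(txs, function(e) sum(e$end - e$start + 1L), integer(1))
    genes[[gid]] <- structure(
      list(gene_id = gid,
           contig = as.character(GenomicRanges::seqnames(gff)[gi]),
           strand = as.character(GenomicRanges::strand(gff)[gi]),
           transcripts = txs,
           longest_transcript_len = if (length(lens)) max(lens) else 0L),
      class = "gene_model")
  }
  unname(genes)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d transcript(s), longest %d bp\n",
              x$gene_id, x$contig, x$strand, length(x$transcripts),
              x$longest_transcript_len))
  invisible(x)
}
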