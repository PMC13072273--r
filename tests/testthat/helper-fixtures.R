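# In-code fixtures shared across the suite.

# small variant table from explicit genotype strings:
# gts is a samples x sites character matrix of "0/0", "0/1", "1/1", "./."
toy_vt <- function(gts, pos = NULL, ref = NULL, alt = NULL,
                   contig = "chr1", info = NULL) {
  gts <- as.matrix(gts)
  n_samp <- nrow(gts); n_site <- ncol(gts)
  a1 <- matrix(NA_integer_, n_samp, n_site)
  a2 <- a1
  for (j in seq_len(n_site)) {
    parts <- strsplit(gts[, j], "/")
    a1[, j] <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    a2[, j] <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  }
  samples <- rownames(gts)
  if (is.null(samples)) samples <- paste0("s", seq_len(n_samp))
  if (is.null(pos)) pos <- seq_len(n_site) * 10L
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("G", n_site)
  variant_table(sites = data.frame(contig = contig, pos = pos,
                                   ref = ref, alt = alt),
                a1 = a1, a2 = a2, samples = samples, info = info)
}

# write VCF text lines for a handful of records
write_vcf_fixture <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
    "##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description=\"hs\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"mqrs\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"rprs\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(pos, ref, alt, gts, info = ".", chrom = "chr1") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")
}

# brute-force diagnostic-site oracle: enumerate (site, pop, allele)
oracle_diagnostic_sites <- function(vt, popmap, t) {
  pops <- unique(unname(popmap[vt$samples]))
  hits <- list(); k <- 0L
  for (s in seq_len(n_sites(vt))) {
    for (p in pops) {
      for (al in c("ref", "alt")) {
        haf_f <- compute_haf(vt, popmap, p, s, al)
        if (is.na(haf_f) || haf_f < t) next
        opp <- if (al == "ref") "alt" else "ref"
        ok <- TRUE; min_other <- 1
        for (q in setdiff(pops, p)) {
          h <- compute_haf(vt, popmap, q, s, opp)
          if (is.na(h) || h < t) { ok <- FALSE; break }
          min_other <- min(min_other, h)
        }
        if (!ok) next
        k <- k + 1L
        hits[[k]] <- data.frame(
          contig = vt$sites$contig[s], pos = vt$sites$pos[s],
          focal_pop = p,
          focal_allele = if (al == "ref") vt$sites$ref[s] else
            vt$sites$alt[s])
      }
    }
  }
  if (k == 0) return(data.frame(contig = character(0), pos = integer(0),
                                focal_pop = character(0),
                                focal_allele = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$contig, out$pos, out$focal_pop), , drop = FALSE]
}

# random variant table + popmap for property tests
random_instance <- function(n_samp, n_site, n_pops, miss_rate = 0.1) {
  a1 <- matrix(sample(0:1, n_samp * n_site, replace = TRUE),
               n_samp, n_site)
  a2 <- matrix(sample(0:1, n_samp * n_site, replace = TRUE),
               n_samp, n_site)
  miss <- matrix(runif(n_samp * n_site) < miss_rate, n_samp, n_site)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  samples <- paste0("s", seq_len(n_samp))
  vt <- variant_table(
    sites = data.frame(contig = "c1", pos = seq_len(n_site),
                       ref = "A", alt = "G"),
    a1 = a1, a2 = a2, samples = samples)
  pops <- paste0("P", seq_len(n_pops))
  popmap <- setNames(sample(rep(pops, length.out = n_samp)), samples)
  list(vt = vt, popmap = popmap)
}

diag_key <- function(d) paste(d$contig, d$pos, d$focal_pop, d$focal_allele)
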