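test_that("HAF counts homozygotes over genotyped members", {
  # four 1/1 and one 0/1 -> HAF(alt) = 4/5
  vt <- toy_vt(cbind(c("1/1", "1/1", "1/1", "1/1", "0/1")))
  pm <- setNames(rep("P", 5), vt$samples)
  expect_equal(compute_haf(vt, pm, "P", 1, "alt"), 0.8)
  expect_equal(compute_haf(vt, pm, "P", 1, "ref"), 0)
  # all 0/0 -> HAF(ref) = 1
  vt2 <- toy_vt(cbind(rep("0/0", 4)))
  pm2 <- setNames(rep("P", 4), vt2$samples)
  expect_equal(compute_haf(vt2, pm2, "P", 1, "ref"), 1)
  # partition: HAF(ref) + HAF(alt) <= 1, equality iff no hets
  vt3 <- toy_vt(cbind(c("0/0", "1/1", "0/1", "1/1")))
  pm3 <- setNames(rep("P", 4), vt3$samples)
  expect_lt(compute_haf(vt3, pm3, "P", 1, "ref") +
              compute_haf(vt3, pm3, "P", 1, "alt"), 1)
  # missing genotypes drop from the default denominator, not from "all"
  vt4 <- toy_vt(cbind(c("1/1", "1/1", "./.", "./.")))
  pm4 <- setNames(rep("P", 4), vt4$samples)
  expect_equal(compute_haf(vt4, pm4, "P", 1, "alt"), 1)
  expect_equal(compute_haf(vt4, pm4, "P", 1, "alt",
                           denominator = "all"), 0.5)
})

test_that("diagnostic scan applies HAF threshold and opposite fixation", {
  gts <- rbind(a1 = "1/1", a2 = "1/1", a3 = "1/1", a4 = "1/1",
               a5 = "1/1", b1 = "0/0", b2 = "0/0", b3 = "0/0")
  pm <- setNames(c(rep("A", 5), rep("B", 3)), rownames(gts))
  # fixed difference: diagnostic for A (alt) and B (ref) at t = 1
  ds <- find_diagnostic_sites(toy_vt(gts), pm, t = 1.0)
  expect_equal(nrow(ds), 2)
  expect_setequal(ds$focal_pop, c("A", "B"))
  expect_equal(ds$focal_allele[ds$focal_pop == "A"], "G")
  expect_equal(ds$focal_allele[ds$focal_pop == "B"], "A")

  # 4/5 hom-alt in A: reported at t = 0.8, absent at t = 0.9
  gts2 <- gts; gts2["a5", 1] <- "0/1"
  ds08 <- find_diagnostic_sites(toy_vt(gts2), pm, t = 0.8)
  expect_true("A" %in% ds08$focal_pop)
  ds09 <- find_diagnostic_sites(toy_vt(gts2), pm, t = 0.9)
  expect_false("A" %in% ds09$focal_pop)
  expect_equal(ds08$focal_haf[ds08$focal_pop == "A"], 0.8)

  # one heterozygote in B defeats opposite fixation at t = 1
  gts3 <- gts; gts3["b1", 1] <- "0/1"
  expect_false("A" %in%
                 find_diagnostic_sites(toy_vt(gts3), pm, t = 1)$focal_pop)
})

test_that("diagnostic scan equals the brute-force oracle on random instances", {
  set.seed(2024)
  for (i in 1:25) {
    inst <- random_instance(sample(6:20, 1), sample(10:60, 1),
                            sample(2:4, 1), miss_rate = 0.15)
    t <- sample(c(0.8, 0.9, 1.0), 1)
    got <- find_diagnostic_sites(inst$vt, inst$popmap, t)
    want <- oracle_diagnostic_sites(inst$vt, inst$popmap, t)
    expect_identical(diag_key(got), diag_key(want))
  }
})

test_that("raising the HAF threshold never adds a diagnostic site", {
  set.seed(7)
  for (i in 1:10) {
    inst <- random_instance(12, 50, 3, miss_rate = 0.1)
    d8 <- find_diagnostic_sites(inst$vt, inst$popmap, 0.8)
    d9 <- find_diagnostic_sites(inst$vt, inst$popmap, 0.9)
    d10 <- find_diagnostic_sites(inst$vt, inst$popmap, 1.0)
    expect_true(all(diag_key(d9) %in% diag_key(d8)))
    expect_true(all(diag_key(d10) %in% diag_key(d9)))
  }
})

test_that("gene annotation gates sites, supports no-annotation mode", {
  sites <- data.frame(contig = "chr1", pos = c(50L, 150L, 500L),
                      focal_pop = "A", focal_allele = "G",
                      counter_allele = "A", focal_haf = 1,
                      min_other_haf = 1, gene_id = NA_character_)
  class(sites) <- c("diagnostic_sites", "data.frame")
  genes <- list(
    structure(list(gene_id = "target", contig = "chr1", strand = "+",
                   transcripts = list(t1 = data.frame(start = 40L,
                                                      end = 60L)),
                   longest_transcript_len = 21L),
              class = "gene_model"),
    structure(list(gene_id = "other", contig = "chr1", strand = "+",
                   transcripts = list(t1 = data.frame(start = 140L,
                                                      end = 160L)),
                   longest_transcript_len = 21L),
              class = "gene_model"))
  out <- annotate_sites_with_genes(sites, genes, targets = "target")
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 50L)
  expect_equal(out$gene_id, "target")
  # site in a non-target gene dropped; intergenic site dropped
  out_all <- annotate_sites_with_genes(sites, genes, targets = NULL)
  expect_equal(nrow(out_all), 2)
  # no-annotation mode passes everything through ungated
  out_na <- annotate_sites_with_genes(sites, NULL)
  expect_equal(nrow(out_na), 3)
  expect_true(all(is.na(out_na$gene_id)))
})

test_that("amplicon extraction is 2*flank+1 centred on the site", {
  set.seed(8)
  ref <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3000,
                               replace = TRUE), collapse = ""))
  site <- data.frame(contig = "chr1", pos = 1500L)
  amp <- extract_amplicon(ref, site, flank = 900)
  expect_equal(nchar(amp$sequence), 1801L)
  expect_equal(amp$site_offset, 900L)
  expect_equal(substr(amp$sequence, 901, 901),
               unname(substr(ref, 1500, 1500)))

  amp10 <- extract_amplicon(ref, site, flank = 10)
  expect_equal(nchar(amp10$sequence), 21L)
  expect_equal(substr(amp10$sequence, 11, 11),
               unname(substr(ref, 1500, 1500)))

  # too close to the contig end: skipped with a warning, never truncated
  short_ref <- c(chr1 = unname(substr(ref, 1, 500)))
  expect_warning(
    out <- extract_amplicon(short_ref, data.frame(contig = "chr1",
                                                  pos = 100L),
                            flank = 900), "skipped")
  expect_null(out)
})

test_that("nearest-neighbor Tm matches frozen reference values", {
  # reference values from an independent implementation of the same
  # SantaLucia 1998 model (50 mM Na+, 0.25 uM total strand)
  expect_equal(primer_tm("TATCAGAGGAGGGATCAAATGA"), 51.8224,
               tolerance = 1e-3)
  expect_equal(primer_tm("ACGGAGCGTATTCGATACAGAG"), 56.0095,
               tolerance = 1e-3)
  expect_equal(primer_tm("GGTGAAACTAATCCACCCCCTT"), 56.0066,
               tolerance = 1e-3)
  expect_equal(primer_tm("ACTTTTGCAGATGGATATGGAA"), 51.8623,
               tolerance = 1e-3)
  expect_equal(primer_tm("GCGCGCATATATGCGCGCAT"), 61.7785,
               tolerance = 1e-3)
})

test_that("published-style primer passes size and GC validators", {
  p <- "TATCAGAGGAGGGATCAAATGA"
  expect_equal(nchar(p), 22L)
  expect_true(nchar(p) >= 20 && nchar(p) <= 26)
  expect_equal(gc_percent(p), 100 * 9 / 22, tolerance = 1e-9)
  expect_true(gc_percent(p) >= 30 && gc_percent(p) <= 70)
})

test_that("designed primer pairs satisfy every constraint and span the site", {
  set.seed(99)
  ref <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 4000,
                               replace = TRUE), collapse = ""))
  site <- data.frame(contig = "chr1", pos = 2000L)
  amp <- extract_amplicon(ref, site, flank = 900)
  pc <- primer_constraints()
  pp <- design_primer_pairs(amp, pc, max_pairs = 10)
  expect_gt(nrow(pp), 0)
  for (i in seq_len(nrow(pp))) {
    expect_true(nchar(pp$left_seq[i]) >= 20 && nchar(pp$left_seq[i]) <= 26)
    expect_true(nchar(pp$right_seq[i]) >= 20 && nchar(pp$right_seq[i]) <= 26)
    expect_true(pp$tm_left[i] >= 52 && pp$tm_left[i] <= 62)
    expect_true(pp$tm_right[i] >= 52 && pp$tm_right[i] <= 62)
    expect_true(pp$gc_left[i] >= 30 && pp$gc_left[i] <= 70)
    expect_true(pp$gc_right[i] >= 30 && pp$gc_right[i] <= 70)
    expect_lte(abs(pp$tm_left[i] - pp$tm_right[i]), 5)
    expect_true(pp$product_len[i] >= 150 && pp$product_len[i] <= 900)
    # product spans the diagnostic site
    expect_lt(pp$left_start[i] + nchar(pp$left_seq[i]), amp$site_offset + 1)
    expect_gt(pp$right_start[i], amp$site_offset)
    expect_gte(pp$right_start[i] + nchar(pp$right_seq[i]) -
                 pp$left_start[i], pp$product_len[i])
    # reported right primer is the reverse complement of the template
    templ <- substr(amp$sequence, pp$right_start[i] + 1,
                    pp$right_start[i] + nchar(pp$right_seq[i]))
    expect_equal(pp$right_seq[i], snptrace:::revcomp(templ))
  }

  # infeasible composition: poly-A amplicon has no GC-valid primer
  polyA <- structure(list(site = site,
                          sequence = strrep("A", 1801),
                          site_offset = 900L),
                     class = "amplicon_candidate")
  pp0 <- design_primer_pairs(polyA, pc)
  expect_equal(nrow(pp0), 0)
  expect_match(attr(pp0, "constraint_report"), "left primer")
})

test_that("panel assignment calls planted samples and rejects hybrids", {
  sim <- simulate_traceability_data(sim_config(seed = 41))
  panel <- find_diagnostic_sites(sim$vt, sim$popmap, t = 1.0)
  # every sample with its full panel typed is called to its own pop
  for (s in sim$vt$samples[c(1, 9, 17)]) {
    asg <- assign_population(panel, sim$vt, s)
    expect_equal(asg$call, unname(sim$popmap[s]))
    expect_equal(asg$score, 1)
  }
  # an F1 hybrid (heterozygous at every marker) is unassigned
  vt_h <- sim$vt
  idx <- match(paste(panel$contig, panel$pos),
               paste(vt_h$sites$contig, vt_h$sites$pos))
  vt_h$a1[1, idx] <- 0L; vt_h$a2[1, idx] <- 1L
  asg_h <- assign_population(panel, vt_h, vt_h$samples[1])
  expect_equal(asg_h$call, "unassigned")
  # a sample typed at no marker is an error
  vt_m <- sim$vt
  vt_m$a1[2, idx] <- NA_integer_; vt_m$a2[2, idx] <- NA_integer_
  vt_m <- vt_m[idx, ]
  expect_error(assign_population(panel, vt_m, vt_m$samples[2]),
               "no panel marker")
})

test_that("pipeline runs end to end, is deterministic, and supports no-GFF mode", {
  sim <- simulate_traceability_data(sim_config(seed = 7))
  panel <- run_traceability_pipeline(sim$vt, sim$popmap, sim$ref,
                                     gff = sim$genes, haf_t = 1.0)
  expect_s3_class(panel, "trace_panel")
  expect_setequal(panel$table$Pop, unique(unname(sim$popmap)))
  expect_true(all(c("Pop", "Gene", "Mutation", "Left Primer",
                    "Right Primer") %in% names(panel$table)))
  # re-run on the same inputs is byte-identical
  panel2 <- run_traceability_pipeline(sim$vt, sim$popmap, sim$ref,
                                      gff = sim$genes, haf_t = 1.0)
  expect_identical(panel$table, panel2$table)

  # no-annotation mode still yields markers for every population
  panel_na <- run_traceability_pipeline(sim$vt, sim$popmap, sim$ref,
                                        gff = NULL, haf_t = 1.0)
  expect_setequal(panel_na$table$Pop, unique(unname(sim$popmap)))
  expect_true(all(panel_na$table$Gene == ""))
})
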