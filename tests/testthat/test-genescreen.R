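toy_gene <- function(gene_id = "g1", contig = "chr1", strand = "+",
                     exons = data.frame(start = 1L, end = 4L)) {
  lens <- sum(exons$end - exons$start + 1L)
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 transcripts = list(t1 = exons),
                 longest_transcript_len = lens),
            class = "gene_model")
}

test_that("long-transcript selection uses a strict 2000 bp bound", {
  mk <- function(id, len) structure(
    list(gene_id = id, longest_transcript_len = len),
    class = "gene_model")
  genes <- list(mk("a", 2500L), mk("b", 2000L), mk("c", 1999L),
                mk("d", 2001L))
  kept <- select_long_transcript_genes(genes)
  expect_equal(vapply(kept, `[[`, "", "gene_id"), c("a", "d"))
  expect_equal(select_long_transcript_genes(list()), list())
})

test_that("sample consensus substitutes hom-alt, IUPAC-codes hets, honors strand", {
  ref <- c(chr1 = "ACGTACGT")
  gene <- toy_gene(exons = data.frame(start = 1L, end = 4L))
  # hom-alt C->T at pos 2 ("offset 2" in 1-based): ACGT -> ATGT
  vt <- toy_vt(rbind(s1 = "1/1", s2 = "0/1", s3 = "0/0"),
               pos = 2L, ref = "C", alt = "T")
  expect_equal(build_sample_consensus("s1", gene, ref, vt), "ATGT")
  # heterozygous C/T -> Y
  expect_equal(build_sample_consensus("s2", gene, ref, vt), "AYGT")
  expect_equal(build_sample_consensus("s3", gene, ref, vt), "ACGT")

  # minus strand: reference exon AACC reverse-complements to GGTT
  ref2 <- c(chr1 = "AACCGGTT")
  gene_m <- toy_gene(strand = "-",
                     exons = data.frame(start = 1L, end = 4L))
  vt0 <- toy_vt(rbind(s1 = "0/0"), pos = 6L, ref = "G", alt = "A")
  expect_equal(build_sample_consensus("s1", gene_m, ref2, vt0), "GGTT")

  # spliced exons concatenate in transcript order
  gene_sp <- toy_gene(exons = data.frame(start = c(1L, 7L),
                                         end = c(2L, 8L)))
  expect_equal(build_sample_consensus("s1", gene_sp, ref2, vt0), "AATT")

  # indel alleles are skipped with a warning
  vt_ind <- toy_vt(rbind(s1 = "1/1"), pos = 2L, ref = "A", alt = "AT")
  expect_warning(
    out <- build_sample_consensus("s1", gene, ref2, vt_ind), "indel")
  expect_equal(out, "AACC")
  # consensus length always equals the exon sum
  expect_equal(nchar(out), 4L)
})

test_that("NJ gene tree recovers an additive quartet and ignores input order", {
  # sequences built so that (a,b) and (c,d) are cherries
  seqs <- c(a = "AAAAAAAAAATT", b = "AAAAAAAAAACC",
            c = "GGGGGGGGGGTT", d = "GGGGGGGGGGCC")
  tr <- build_gene_tree(seqs)
  expect_s3_class(tr, "phylo")
  expect_equal(robinson_foulds(tr, ape::read.tree(text = "((a,b),(c,d));")), 0)
  # permuting the input leaves the unrooted topology unchanged
  tr_perm <- build_gene_tree(seqs[c(3, 1, 4, 2)])
  expect_equal(robinson_foulds(tr, tr_perm), 0)
  # identical sequences sit on a zero-length cherry
  seqs2 <- c(seqs, e = "GGGGGGGGGGCC")
  tr2 <- build_gene_tree(seqs2)
  m <- ape::cophenetic.phylo(tr2)
  expect_equal(m["d", "e"], 0)
})

test_that("IUPAC-ambiguous positions are excluded from pairwise distances", {
  # Y at position 1 of 'b' is not comparable; remaining 4 positions differ at 2
  seqs <- c(a = "ACGTA", b = "YCGAA", c = "ACGTA", d = "TTTTT")
  d <- snptrace:::p_distance_matrix(seqs)
  expect_equal(d["a", "b"], 1 / 4)
  expect_equal(d["a", "c"], 0)
})

test_that("Robinson-Foulds matches hand enumeration and the ape oracle", {
  t_ab <- ape::read.tree(text = "((A,B),(C,D));")
  t_ac <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t_ab, t_ab), 0)
  # each 4-leaf tree has one internal bipartition; they differ -> 2
  expect_equal(robinson_foulds(t_ab, t_ac), 2)
  expect_error(robinson_foulds(ape::read.tree(text = "((A,B),C);"),
                               ape::read.tree(text = "((A,B),C);")),
               "four")

  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    t1 <- ape::rtree(n, tip.label = paste0("L", 1:n))
    t2 <- ape::rtree(n, tip.label = paste0("L", 1:n))
    rf <- robinson_foulds(t1, t2)
    oracle <- as.integer(round(ape::dist.topo(ape::unroot(t1),
                                              ape::unroot(t2))))
    expect_identical(rf, oracle)
    expect_lte(rf, 2 * (n - 3))
    # metric properties: symmetry and identity
    expect_identical(robinson_foulds(t2, t1), rf)
    expect_identical(robinson_foulds(t1, t1), 0L)
  }
  # triangle inequality, spot-checked
  for (i in 1:10) {
    tr <- replicate(3, ape::rtree(8, tip.label = paste0("L", 1:8)),
                    simplify = FALSE)
    d12 <- robinson_foulds(tr[[1]], tr[[2]])
    d23 <- robinson_foulds(tr[[2]], tr[[3]])
    d13 <- robinson_foulds(tr[[1]], tr[[3]])
    expect_lte(d13, d12 + d23)
  }
})

test_that("RF is computed on the pruned shared leaf set", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(robinson_foulds(t1, t2), 0)
})

test_that("length-RF Pearson correlation matches the textbook formula", {
  recs <- data.frame(transcript_len = c(2100, 2500, 3000, 3600, 4200),
                     rf_distance = c(6, 4, 5, 2, 1))
  out <- correlate_length_rf(recs)
  x <- recs$transcript_len; y <- recs$rf_distance
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_stat), df = 3), tolerance = 1e-12)

  # exact anticorrelation
  recs2 <- data.frame(transcript_len = 1:10,
                      rf_distance = 20 - (1:10))
  expect_equal(correlate_length_rf(recs2)$r, -1)

  # independent simulated lengths/distances stay near zero
  set.seed(77)
  recs3 <- data.frame(transcript_len = runif(1000, 2000, 9000),
                      rf_distance = sample(0:20, 1000, replace = TRUE))
  expect_lt(abs(correlate_length_rf(recs3)$r), 0.1)
  expect_error(correlate_length_rf(
    data.frame(transcript_len = c(1, 1, 1), rf_distance = 1:3)),
    "variance")
})

test_that("target-gene selection honors quantile and absolute policies", {
  recs <- data.frame(gene_id = paste0("g", 1:8),
                     transcript_len = seq(4000, 2600, by = -200),
                     rf_distance = c(0, 0, 2, 2, 4, 4, 6, 6))
  expect_equal(select_target_genes(recs), c("g1", "g2"))
  same <- transform(recs, rf_distance = 4)
  expect_equal(select_target_genes(same), same$gene_id)
  expect_equal(select_target_genes(recs, policy = "absolute", max_rf = 0),
               c("g1", "g2"))
})

test_that("genes holding planted diagnostic sites track the species tree better", {
  sim <- simulate_traceability_data(sim_config(
    seed = 13, samples_per_pop = 5, n_background_sites = 300))
  long_genes <- select_long_transcript_genes(sim$genes)
  concat <- vapply(sim$vt$samples, function(s) paste(
    vapply(long_genes, function(g)
      build_sample_consensus(s, g, sim$ref, sim$vt), character(1)),
    collapse = ""), character(1))
  sp_tree <- build_gene_tree(concat)
  screen <- screen_genes(sim$genes[1:6], sim$ref, sim$vt, sp_tree)
  expect_s3_class(screen, "gene_screen")
  has_planted <- vapply(sim$genes[1:6], function(g) {
    ex <- snptrace:::longest_transcript(g)
    any(vapply(sim$truth$pos, function(p)
      any(p >= ex$start & p <= ex$end), logical(1)))
  }, logical(1))
  ids <- vapply(sim$genes[1:6], `[[`, "", "gene_id")
  rf_of <- setNames(screen$rf_distance[match(ids, screen$gene_id)], ids)
  expect_lt(mean(rf_of[has_planted]), mean(rf_of[!has_planted]))
})
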