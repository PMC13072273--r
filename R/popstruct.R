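#' Pairwise normalized identity-by-state kinship
#'
#' Raw IBS between two diploid genotypes at one site is the number of
#' alleles identical by state divided by 2 (0, 0.5 or 1); the pairwise
#' value is the mean over sites where both samples are genotyped. With
#' dosages d1, d2 this is `1 - |d1 - d2| / 2`. The "normalized" matrix
#' rescales the raw values linearly so the smallest off-diagonal entry
#' maps to 0 and self-similarity to 1, preserving the ordering used in
#' kinship heatmaps.
#'
#' @param vt a `variant_table` with at least two samples.
#' @return object of class `kinship_matrix`: list with `raw` and
#'   `normalized` square matrices (sample ids as dimnames). Pairs that
#'   share no genotyped site are `NA` and flagged in `$undefined_pairs`.
#' @export
compute_ibs_kinship <- function(vt) {
  if (n_samples(vt) < 2) stop("need at least two samples")
  ds <- dosage(vt)
  n <- nrow(ds)
  raw <- matrix(NA_real_, n, n, dimnames = list(vt$samples, vt$samples))
  for (i in seq_len(n)) {
    for (j in i:n) {
      both <- !is.na(ds[i, ]) & !is.na(ds[j, ])
      raw[i, j] <- raw[j, i] <- if (any(both))
        mean(1 - abs(ds[i, both] - ds[j, both]) / 2) else NA_real_
    }
  }
  off <- raw[upper.tri(raw)]
  undefined <- which(is.na(raw) & upper.tri(raw), arr.ind = TRUE)
  lo <- suppressWarnings(min(off, na.rm = TRUE))
  norm <- if (is.finite(lo) && lo < 1) (raw - lo) / (1 - lo) else
    matrix(1, n, n, dimnames = dimnames(raw))
  diag(norm) <- 1
  structure(list(raw = raw, normalized = norm,
                 undefined_pairs = undefined),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d samples (normalized IBS)\n",
              nrow(x$raw)))
  print(round(x$normalized, 3))
  invisible(x)
}

#' Genotype principal component analysis
#'
#' Genotypes are coded as 0/1/2 alternate-allele dosage; missing calls
#' are imputed with the per-site mean; columns are centred (and, with
#' `scaling = "patterson"`, divided by `sqrt(p(1-p))` with `p` the
#' alt-allele frequency). Components come from the eigendecomposition
#' of the sample covariance of this matrix; variance fractions are
#' eigenvalues over their total.
#'
#' @param vt a `variant_table`.
#' @param n_components number of components to return (clipped with a
#'   warning to `min(samples, sites) - 1`).
#' @param scaling `"center"` (default) or `"patterson"`.
#' @return object of class `pca_result`: `coordinates` (samples x
#'   components) and `variance_fraction`.
#' @export
compute_pca <- function(vt, n_components = 2,
                        scaling = c("center", "patterson")) {
  scaling <- match.arg(scaling)
  if (n_samples(vt) < 2) stop("need at least two samples")
  ds <- dosage(vt)
  mu <- colMeans(ds, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  x <- sweep(ds, 2, mu)
  x[is.na(x)] <- 0
  if (scaling == "patterson") {
    p <- mu / 2
    sd_p <- sqrt(pmax(p * (1 - p), 0))
    keep <- sd_p > 0
    x <- sweep(x[, keep, drop = FALSE], 2, sd_p[keep], "/")
  }
  max_k <- max(1L, min(dim(x)) - 1L)
  if (n_components > max_k) {
    warning(sprintf("n_components clipped from %d to %d",
                    n_components, max_k))
    n_components <- max_k
  }
  cv <- stats::cov(t(x))              # samples x samples
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  coords <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  dimnames(coords) <- list(vt$samples,
                           paste0("PC", seq_len(n_components)))
  structure(list(coordinates = coords,
                 variance_fraction =
                   ev[seq_len(n_components)] / sum(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

# per-population alt-allele frequencies at every site; pops in rows
pop_allele_freqs <- function(vt, popmap) {
  miss <- setdiff(vt$samples, names(popmap))
  if (length(miss)) stop("samples missing from popmap: ",
                         paste(miss, collapse = ", "))
  pops <- unique(unname(popmap[vt$samples]))
  ds <- dosage(vt)
  freq <- matrix(NA_real_, length(pops), n_sites(vt),
                 dimnames = list(pops, NULL))
  for (p in pops) {
    rows <- vt$samples[popmap[vt$samples] == p]
    sub <- ds[rows, , drop = FALSE]
    called <- colSums(!is.na(sub))
    freq[p, ] <- ifelse(called > 0,
                        colSums(sub, na.rm = TRUE) / (2 * called),
                        NA_real_)
  }
  freq
}

#' Patterson's D (ABBA-BABA) statistic with block jackknife
#'
#' Sites are polarized by the outgroup: the outgroup's major allele is
#' taken as ancestral, and sites where the outgroup's minor-allele
#' frequency exceeds `outgroup_poly_max` are skipped. With derived
#' allele frequencies p1, p2, p3, p4 per site,
#' `ABBA = sum (1-p1) p2 p3 (1-p4)` and
#' `BABA = sum p1 (1-p2) p3 (1-p4)`;
#' `D = (ABBA - BABA) / (ABBA + BABA)`. The Z score comes from a
#' delete-one jackknife over contiguous equal-size site blocks.
#'
#' @param vt a `variant_table`.
#' @param popmap named character vector (sample -> population).
#' @param p1,p2,p3,outgroup population labels; a label naming a single
#'   sample's population covers the per-individual case.
#' @param block_size sites per jackknife block.
#' @param outgroup_poly_max maximum outgroup minor-allele frequency for
#'   a site to be polarizable.
#' @return object of class `dstat_result` with fields `trio`, `abba`,
#'   `baba`, `d`, `z`, `p`, `n_blocks`, `n_sites_used`. `d` is `NA`
#'   (flagged) when `abba + baba == 0`.
#' @export
compute_d_statistic <- function(vt, popmap, p1, p2, p3, outgroup,
                                block_size = 1000,
                                outgroup_poly_max = 0.1) {
  labs <- c(p1, p2, p3, outgroup)
  if (outgroup %in% c(p1, p2, p3)) stop("outgroup must be distinct")
  freq <- pop_allele_freqs(vt, popmap)
  if (!all(labs %in% rownames(freq)))
    stop("population label(s) absent from popmap: ",
         paste(setdiff(labs, rownames(freq)), collapse = ", "))
  f <- freq[labs, , drop = FALSE]
  usable <- colSums(is.na(f)) == 0
  # polarize: ancestral = outgroup major allele
  po <- f[4, ]
  polarizable <- usable & pmin(po, 1 - po) <= outgroup_poly_max
  flip <- polarizable & po > 0.5          # alt is ancestral: flip to derived
  d_f <- f[, polarizable, drop = FALSE]
  d_f[, flip[polarizable]] <- 1 - d_f[, flip[polarizable]]
  q1 <- d_f[1, ]; q2 <- d_f[2, ]; q3 <- d_f[3, ]; q4 <- d_f[4, ]
  abba_s <- (1 - q1) * q2 * q3 * (1 - q4)
  baba_s <- q1 * (1 - q2) * q3 * (1 - q4)
  abba <- sum(abba_s); baba <- sum(baba_s)
  tot <- abba + baba
  d <- if (tot > 0) (abba - baba) / tot else NA_real_

  m <- length(abba_s)
  z <- p <- NA_real_; n_blocks <- 0L
  if (tot > 0 && m >= 2) {
    blk <- ceiling(seq_len(m) / block_size)
    n_blocks <- max(blk)
    if (n_blocks >= 2) {
      ab_b <- tapply(abba_s, blk, sum); ba_b <- tapply(baba_s, blk, sum)
      d_del <- (abba - ab_b - (baba - ba_b)) /
        pmax(tot - ab_b - ba_b, .Machine$double.eps)
      g <- n_blocks
      var_j <- (g - 1) / g * sum((d_del - mean(d_del))^2)
      if (var_j > 0) {
        z <- d / sqrt(var_j)
        p <- 2 * stats::pnorm(-abs(z))
      } else if (d == 0) { z <- 0; p <- 1 }
    }
  }
  structure(list(trio = c(P1 = p1, P2 = p2, P3 = p3,
                          outgroup = outgroup),
                 abba = abba, baba = baba, d = d, z = z, p = p,
                 n_blocks = n_blocks, n_sites_used = m),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D statistic (((%s,%s),%s),%s)\n", x$trio[1], x$trio[2],
              x$trio[3], x$trio[4]))
  cat(sprintf("  ABBA %.3f  BABA %.3f  D = %s  Z = %s  p = %s  (%d sites, %d blocks)\n",
              x$abba, x$baba, format(x$d, digits = 4),
              format(x$z, digits = 3), format(x$p, digits = 3),
              x$n_sites_used, x$n_blocks))
  invisible(x)
}

#' f4-ratio admixture proportion estimate
#'
#' Estimates the fraction `alpha` of ancestry that a test population X
#' derives from source B (versus the C side), as the ratio
#' `f4(A, O; X, C) / f4(A, O; B, C)` with
#' `f4 = sum (pA - pO)(pX - pC)` over sites. A is an unadmixed
#' reference on B's side of the tree, O the outgroup, C the second
#' source's sister. A block jackknife over contiguous sites gives the
#' standard error.
#'
#' @param vt a `variant_table`.
#' @param popmap named character vector (sample -> population).
#' @param a,b,x,c_,outgroup the five distinct population labels
#'   (roles as above; `c_` because `c` is taken in R).
#' @param block_size sites per jackknife block.
#' @return object of class `f4ratio_result` with `alpha`, `se`,
#'   `f4_num`, `f4_den`; `alpha` is `NA` (flagged) when the
#'   denominator is zero.
#' @export
compute_f4_ratio <- function(vt, popmap, a, b, x, c_, outgroup,
                             block_size = 1000) {
  labs <- c(a, b, x, c_, outgroup)
  if (anyDuplicated(labs)) stop("the five labels must be distinct")
  freq <- pop_allele_freqs(vt, popmap)
  if (!all(labs %in% rownames(freq)))
    stop("population label(s) absent from popmap")
  f <- freq[labs, , drop = FALSE]
  use <- colSums(is.na(f)) == 0
  f <- f[, use, drop = FALSE]
  num_s <- (f[1, ] - f[5, ]) * (f[3, ] - f[4, ])
  den_s <- (f[1, ] - f[5, ]) * (f[2, ] - f[4, ])
  num <- sum(num_s); den <- sum(den_s)
  alpha <- if (abs(den) > 0) num / den else NA_real_
  se <- NA_real_
  m <- length(num_s)
  if (!is.na(alpha) && m >= 2) {
    blk <- ceiling(seq_len(m) / block_size)
    g <- max(blk)
    if (g >= 2) {
      n_b <- tapply(num_s, blk, sum); d_b <- tapply(den_s, blk, sum)
      ok <- abs(den - d_b) > 0
      if (sum(ok) == g) {
        a_del <- (num - n_b) / (den - d_b)
        se <- sqrt((g - 1) / g * sum((a_del - mean(a_del))^2))
      }
    }
  }
  structure(list(labels = c(A = a, B = b, X = x, C = c_,
                            outgroup = outgroup),
                 alpha = alpha, se = se, f4_num = num, f4_den = den,
                 n_sites_used = m),
            class = "f4ratio_result")
}

#' @export
print.f4ratio_result <- function(x, ...) {
  cat(sprintf("f4-ratio: alpha(%s from %s) = %s +/- %s  (f4 num %.4f / den %.4f, %d sites)\n",
              x$labels["X"], x$labels["B"], format(x$alpha, digits = 4),
              format(x$se, digits = 3), x$f4_num, x$f4_den,
              x$n_sites_used))
  invisible(x)
}
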