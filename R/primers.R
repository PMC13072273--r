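# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol*K), keyed by the 5'->3' top-strand
# dinucleotide; complementary stacks share values.
nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer melting temperature (nearest-neighbor model)
#'
#' Duplex Tm from SantaLucia (1998) unified nearest-neighbor
#' thermodynamics with initiation and terminal A/T terms, a
#' salt-corrected entropy (`dS + 0.368 (N-1) ln[Na+]`) and
#' `Tm = 1000 dH / (dS' + R ln(C/4)) - 273.15` for a non-
#' self-complementary oligo at total strand concentration `conc_m`.
#'
#' @param seq_str primer sequence, 5'->3', A/C/G/T only.
#' @param na_m monovalent cation concentration (mol/L).
#' @param conc_m total primer concentration (mol/L).
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(seq_str, na_m = 0.05, conc_m = 0.25e-6) {
  s <- toupper(seq_str)
  b <- strsplit(s, "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("primer sequence must be A/C/G/T only")
  n <- length(b)
  if (n < 2) stop("primer too short for the nearest-neighbor model")
  steps <- paste0(b[-n], b[-1])
  dh <- sum(nn_dh[steps])
  ds <- sum(nn_ds[steps])
  for (term in c(b[1], b[n])) {          # initiation at each duplex end
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else                       { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds_salt <- ds + 0.368 * (n - 1) * log(na_m)
  1000 * dh / (ds_salt + 1.987 * log(conc_m / 4)) - 273.15
}

#' GC content of a sequence, in percent
#' @param seq_str sequence string.
#' @return percentage of G+C bases.
#' @export
gc_percent <- function(seq_str) {
  b <- strsplit(toupper(seq_str), "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' PCR primer design constraints
#'
#' Min/opt/max triples for primer size, melting temperature and GC
#' content, plus product-size bounds and the maximum Tm difference
#' within a pair. Defaults are the panel-design settings: size
#' 20/22/26 nt, Tm 52/56/62 degrees C, GC 30/50/70 percent, product
#' 150-900 bp, pair dTm <= 5 degrees C.
#'
#' @param size_min,size_opt,size_max primer length bounds (nt).
#' @param tm_min,tm_opt,tm_max melting-temperature bounds (deg C).
#' @param gc_min,gc_opt,gc_max GC-content bounds (percent).
#' @param product_min,product_max product-size bounds (bp).
#' @param pair_tm_diff_max maximum |Tm_left - Tm_right| (deg C).
#' @return object of class `primer_constraints`.
#' @export
primer_constraints <- function(size_min = 20, size_opt = 22,
                               size_max = 26,
                               tm_min = 52, tm_opt = 56, tm_max = 62,
                               gc_min = 30, gc_opt = 50, gc_max = 70,
                               product_min = 150, product_max = 900,
                               pair_tm_diff_max = 5) {
  pc <- list(size_min = size_min, size_opt = size_opt,
             size_max = size_max,
             tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
             gc_min = gc_min, gc_opt = gc_opt, gc_max = gc_max,
             product_min = product_min, product_max = product_max,
             pair_tm_diff_max = pair_tm_diff_max)
  for (tri in list(c("size_min", "size_opt", "size_max"),
                   c("tm_min", "tm_opt", "tm_max"),
                   c("gc_min", "gc_opt", "gc_max")))
    if (!(pc[[tri[1]]] <= pc[[tri[2]]] && pc[[tri[2]]] <= pc[[tri[3]]]))
      stop("constraint triple violates min <= opt <= max: ",
           paste(tri, collapse = "/"))
  structure(pc, class = "primer_constraints")
}

# enumerate constraint-satisfying single primers on one side of the
# site; returns data.frame with 0-based start, length, seq, tm, gc,
# penalty. `side` = "left" keeps windows ending before the site,
# "right" windows starting after it (sequence reported on the minus
# strand for the right side).
enumerate_primers <- function(amp_seq, site_offset, pc, side) {
  n <- nchar(amp_seq)
  cand <- list(); k <- 0L
  for (len in pc$size_min:pc$size_max) {
    starts <- if (side == "left") {
      if (site_offset - len < 0) integer(0) else 0:(site_offset - len)
    } else {
      if (site_offset + 1 > n - len) integer(0) else
        (site_offset + 1):(n - len)
    }
    for (st in starts) {
      sq <- substr(amp_seq, st + 1, st + len)
      if (grepl("[^ACGTacgt]", sq)) next
      gc <- gc_percent(sq)
      if (gc < pc$gc_min || gc > pc$gc_max) next
      tm <- primer_tm(sq)
      if (tm < pc$tm_min || tm > pc$tm_max) next
      k <- k + 1L
      cand[[k]] <- data.frame(
        start = st, len = len,
        seq = if (side == "left") sq else revcomp(sq),
        tm = tm, gc = gc,
        penalty = abs(len - pc$size_opt) + abs(tm - pc$tm_opt) +
          0.2 * abs(gc - pc$gc_opt))
    }
  }
  if (k == 0) return(NULL)
  out <- do.call(rbind, cand)
  out[order(out$penalty), , drop = FALSE]
}

#' Design constraint-satisfying primer pairs for an amplicon
#'
#' Enumerates candidate left primers strictly upstream and right
#' primers strictly downstream of the diagnostic site, rejects any
#' that violate the size/Tm/GC constraints, and pairs them under the
#' product-size bounds and pair Tm-difference limit so that every
#' product contains the diagnostic site. Pairs are ranked by the sum
#' of the single-primer penalties (weighted deviation from the size,
#' Tm and GC optima) plus the pair Tm mismatch; the best `max_pairs`
#' are returned. Right primers are reported 5'->3' on the minus
#' strand (the usual reporting convention).
#'
#' @param amp an `amplicon_candidate` ([extract_amplicon()]).
#' @param pc a [primer_constraints()] object.
#' @param max_pairs maximum number of pairs to return.
#' @param beam number of top-ranked single primers per side considered
#'   during pairing.
#' @return data.frame (class `primer_pairs`) with columns `left_seq`,
#'   `right_seq`, `left_start`, `right_start` (0-based offsets in the
#'   amplicon), `tm_left`, `tm_right`, `gc_left`, `gc_right`,
#'   `product_len`, `penalty`; zero rows (with a
#'   `"constraint_report"` attribute naming the binding constraint)
#'   when no pair is feasible.
#' @export
design_primer_pairs <- function(amp, pc = primer_constraints(),
                                max_pairs = 5, beam = 40) {
  stopifnot(inherits(amp, "amplicon_candidate"))
  empty <- function(why) {
    out <- data.frame(left_seq = character(0), right_seq = character(0),
                      left_start = integer(0), right_start = integer(0),
                      tm_left = numeric(0), tm_right = numeric(0),
                      gc_left = numeric(0), gc_right = numeric(0),
                      product_len = integer(0), penalty = numeric(0))
    attr(out, "constraint_report") <- why
    class(out) <- c("primer_pairs", "data.frame")
    out
  }
  if (nchar(amp$sequence) < pc$product_min)
    return(empty("amplicon shorter than product_min"))
  left <- enumerate_primers(amp$sequence, amp$site_offset, pc, "left")
  if (is.null(left)) return(empty("no feasible left primer (size/Tm/GC)"))
  right <- enumerate_primers(amp$sequence, amp$site_offset, pc, "right")
  if (is.null(right)) return(empty("no feasible right primer (size/Tm/GC)"))
  left <- utils::head(left, beam); right <- utils::head(right, beam)

  pairs <- list(); k <- 0L
  for (i in seq_len(nrow(left))) for (j in seq_len(nrow(right))) {
    prod_len <- right$start[j] + right$len[j] - left$start[i]
    if (prod_len < pc$product_min || prod_len > pc$product_max) next
    dtm <- abs(left$tm[i] - right$tm[j])
    if (dtm > pc$pair_tm_diff_max) next
    k <- k + 1L
    pairs[[k]] <- data.frame(
      left_seq = left$seq[i], right_seq = right$seq[j],
      left_start = left$start[i], right_start = right$start[j],
      tm_left = left$tm[i], tm_right = right$tm[j],
      gc_left = left$gc[i], gc_right = right$gc[j],
      product_len = prod_len,
      penalty = left$penalty[i] + right$penalty[j] + dtm)
  }
  if (k == 0)
    return(empty("no pair within product-size/pair-Tm bounds"))
  out <- do.call(rbind, pairs)
  out <- out[order(out$penalty), , drop = FALSE]
  out <- utils::head(out, max_pairs)
  rownames(out) <- NULL
  class(out) <- c("primer_pairs", "data.frame")
  out
}

#' Assign a sample to a population with a diagnostic-marker panel
#'
#' For every typed panel marker, a match is a genotype homozygous for
#' that marker's focal allele. Each population is scored as matched
#' markers over typed markers of that population; the call is the
#' population with the strictly highest score if it reaches
#' `min_score`, otherwise `"unassigned"`.
#'
#' @param panel a `diagnostic_sites` data.frame (the marker panel).
#' @param vt a `variant_table` containing the sample (sites matched to
#'   the panel by contig and position; panel alleles matched against
#'   the site's ref/alt).
#' @param sample sample id in `vt`.
#' @param min_score minimum matched fraction for a call.
#' @return object of class `panel_assignment`: `sample`, `call`,
#'   `score`, `scores` (per population), `n_typed`, and the per-marker
#'   detail data.frame.
#' @export
assign_population <- function(panel, vt, sample, min_score = 0.8) {
  si <- match(sample, vt$samples)
  if (is.na(si)) stop("unknown sample: ", sample)
  key_vt <- paste(vt$sites$contig, vt$sites$pos)
  idx <- match(paste(panel$contig, panel$pos), key_vt)
  detail <- panel
  detail$typed <- FALSE; detail$matched <- FALSE
  for (i in seq_len(nrow(panel))) {
    s <- idx[i]
    if (is.na(s)) next
    a1 <- vt$a1[si, s]; a2 <- vt$a2[si, s]
    if (is.na(a1)) next
    g_allele <- c(vt$sites$ref[s], vt$sites$alt[s])
    detail$typed[i] <- TRUE
    detail$matched[i] <- (a1 == a2) &&
      g_allele[a1 + 1L] == panel$focal_allele[i]
  }
  if (!any(detail$typed)) stop("no panel marker typed in sample ", sample)
  typed <- detail[detail$typed, , drop = FALSE]
  pops <- unique(panel$focal_pop)
  scores <- vapply(pops, function(p) {
    tp <- typed[typed$focal_pop == p, , drop = FALSE]
    if (nrow(tp) == 0) return(NA_real_)
    mean(tp$matched)
  }, numeric(1))
  call <- "unassigned"; best <- NA_real_
  ok <- which(!is.na(scores))
  if (length(ok)) {
    best <- max(scores[ok])
    top <- names(scores)[!is.na(scores) & scores == best]
    if (length(top) == 1 && best >= min_score) call <- top
  }
  structure(list(sample = sample, call = call, score = best,
                 scores = scores, n_typed = sum(detail$typed),
                 detail = detail),
            class = "panel_assignment")
}

#' @export
print.panel_assignment <- function(x, ...) {
  cat(sprintf("panel_assignment: %s -> %s (score %s, %d markers typed)\n",
              x$sample, x$call, format(x$score, digits = 3), x$n_typed))
  invisible(x)
}
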