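# Exon-strength covariates and the weak-exon comparison: hexamer
# enhancer/silencer coverage, GC-matched partition of carrier vs
# non-carrier exons, group tests, and the display normalization.

#' Validate a hexamer set
#'
#' @param kmers character vector of 6-mers (uppercase ACGT).
#' @param label set label, e.g. `"ESE"` or `"ESS"`.
#' @return character vector with a `label` attribute.
#' @export
hexamer_set <- function(kmers, label = "custom") {
  kmers <- toupper(kmers)
  if (any(nchar(kmers) != 6L) || any(grepl("[^ACGT]", kmers)))
    stop("hexamer sets must contain uppercase ACGT 6-mers")
  structure(unique(kmers), label = label)
}

#' Fraction of exon positions covered by a hexamer set
#'
#' The union of all (possibly overlapping) occurrences of any set
#' member is taken; coverage is the covered fraction of exon length.
#' Exons shorter than 6 nt get coverage 0 with a warning.
#'
#' @param exon_seq character vector of exon sequences.
#' @param hexamers a [hexamer_set()] (or plain character vector of
#'   6-mers).
#' @return numeric vector of fractions in \[0, 1\].
#' @export
motif_coverage <- function(exon_seq, hexamers) {
  hexamers <- hexamer_set(hexamers, label = attr(hexamers, "label") %||%
                            "custom")
  idx <- .kmer_index(hexamers)
  vapply(toupper(exon_seq), function(s) {
    L <- nchar(s)
    if (L < 6L) {
      warning("exon shorter than 6 nt: coverage 0")
      return(0)
    }
    W <- .kmer_codes(s, 6L)
    starts <- which(W[, 1L] %in% idx)
    if (!length(starts)) return(0)
    covered <- unique(unlist(lapply(starts, function(p) p:(p + 5L))))
    length(covered) / L
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GC-matched partition of carrier and non-carrier exons
#'
#' Splits the corpus into exons carrying at least one of the fit's
#' significant motif pairs and exons carrying none, then matches each
#' carrier to a distinct non-carrier with identical integer G+C
#' counts in \emph{both} scanning windows (greedy within GC class,
#' seeded tie-breaking).  Unmatched exons are dropped and logged, so
#' the two returned sets have identical GC histograms in both windows
#' by construction.
#'
#' @param corpus the scanned corpus.
#' @param fit a `bbcooc` fit.
#' @param seed RNG seed for tie-breaking.
#' @return list of class `gc_matched`: `with_pairs` and
#'   `without_pairs` (exon_id vectors of equal length),
#'   `unmatched_with`, `unmatched_without`.
#' @export
gc_matched_partition <- function(corpus, fit, seed = 1L) {
  stopifnot(inherits(fit, "bbcooc"))
  pairing <- fit$pairing
  up <- extract_region(corpus, pairing$upstream)
  dn <- extract_region(corpus, pairing$downstream)
  carrier <- .pair_carriers(up, dn, fit$significant, fit$k)
  gcu <- .gc_count(up)
  gcd <- .gc_count(dn)
  cls <- paste(gcu, gcd)
  rng <- .substream(seed, "gc_match")
  with_idx <- which(carrier)
  without_idx <- which(!carrier)
  m_with <- integer(); m_without <- integer()
  for (cl in unique(cls[with_idx])) {
    a <- with_idx[cls[with_idx] == cl]
    b <- without_idx[cls[without_idx] == cl]
    n <- min(length(a), length(b))
    if (n == 0L) next
    if (length(a) > n) a <- a[rng$sample_int(length(a), n)]
    if (length(b) > n) b <- b[rng$sample_int(length(b), n)]
    m_with <- c(m_with, a); m_without <- c(m_without, b)
  }
  structure(list(
    with_pairs = corpus$exon_id[m_with],
    without_pairs = corpus$exon_id[m_without],
    unmatched_with = corpus$exon_id[setdiff(with_idx, m_with)],
    unmatched_without = corpus$exon_id[setdiff(without_idx, m_without)]),
    class = "gc_matched")
}

# Logical: does each exon carry >= 1 of the pairs (both motifs, binary
# presence in the respective windows)?
.pair_carriers <- function(up, dn, pairs, k) {
  n <- length(up)
  if (!nrow(pairs)) return(rep(FALSE, n))
  PU <- .presence_matrix(up, k)
  PD <- .presence_matrix(dn, k)
  iu <- .kmer_index(pairs$motif_u)
  id <- .kmer_index(pairs$motif_d)
  carrier <- rep(FALSE, n)
  for (r in seq_along(iu))
    carrier <- carrier | (PU[, iu[r]] > 0 & PD[, id[r]] > 0)
  carrier
}

#' Compare splicing-strength features between two exon sets
#'
#' For each requested feature — ESE coverage, ESS coverage, acceptor
#' consensus value, donor consensus value — reports per-group means,
#' standard errors and a two-sided p-value (Welch t-test by default,
#' Mann-Whitney on request).
#'
#' @param corpus the corpus holding the exons.
#' @param setA,setB exon_id vectors (e.g. from
#'   [gc_matched_partition()]); both must be non-empty.
#' @param ese,ess [hexamer_set()]s for coverage features (either may
#'   be `NULL` to skip).
#' @param pwms list with `acceptor` / `donor` [estimate_pwm()] objects
#'   for consensus-value features (`NULL` to skip).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return data.frame of class `strength_comparison`: one row per
#'   feature with `mean_A`, `mean_B`, `se_A`, `se_B`, `p_value`,
#'   `n_A`, `n_B`.
#' @export
compare_exon_strength <- function(corpus, setA, setB, ese = NULL,
                                  ess = NULL, pwms = NULL,
                                  test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (!length(setA) || !length(setB)) stop("both exon sets must be non-empty")
  a <- corpus[match(setA, corpus$exon_id), , drop = FALSE]
  b <- corpus[match(setB, corpus$exon_id), , drop = FALSE]
  if (anyNA(a$exon_id) || anyNA(b$exon_id))
    stop("exon_id not found in corpus")
  feats <- list()
  if (!is.null(ese))
    feats$ese_coverage <- list(motif_coverage(a$exon_seq, ese),
                               motif_coverage(b$exon_seq, ese))
  if (!is.null(ess))
    feats$ess_coverage <- list(motif_coverage(a$exon_seq, ess),
                               motif_coverage(b$exon_seq, ess))
  if (!is.null(pwms)) {
    feats$acceptor_cv <- list(score_splice_site(a$acceptor_window,
                                                pwms$acceptor),
                              score_splice_site(b$acceptor_window,
                                                pwms$acceptor))
    feats$donor_cv <- list(score_splice_site(a$donor_window, pwms$donor),
                           score_splice_site(b$donor_window, pwms$donor))
  }
  if (!length(feats)) stop("no features requested")
  rows <- lapply(names(feats), function(f) {
    va <- feats[[f]][[1L]]; vb <- feats[[f]][[2L]]
    p <- if (isTRUE(all.equal(stats::var(c(va, vb)), 0))) {
      1  # both groups constant and equal: no evidence of difference
    } else if (test == "welch") {
      stats::t.test(va, vb)$p.value
    } else {
      stats::wilcox.test(va, vb, exact = FALSE)$p.value
    }
    data.frame(feature = f, mean_A = mean(va), mean_B = mean(vb),
               se_A = stats::sd(va) / sqrt(length(va)),
               se_B = stats::sd(vb) / sqrt(length(vb)),
               p_value = p, n_A = length(va), n_B = length(vb))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("strength_comparison", "data.frame")
  out
}

#' Display normalization for paired group values
#'
#' Centers a pair of group values (or parallel vectors of them) on
#' the midpoint of the two group means and rescales so that the
#' maximum absolute deviation from that midpoint equals 1; output is
#' always within \[-1, 1\].  A zero-deviation pair maps to (0, 0).
#'
#' @param valuesA,valuesB numeric vectors of equal length.
#' @return list with rescaled `a` and `b`.
#' @export
normalize_for_display <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) == length(valuesB),
            all(is.finite(valuesA)), all(is.finite(valuesB)))
  mid <- (valuesA + valuesB) / 2
  maxdev <- max(abs(c(valuesA - mid, valuesB - mid)))
  if (maxdev == 0) return(list(a = valuesA * 0, b = valuesB * 0))
  list(a = (valuesA - mid) / maxdev, b = (valuesB - mid) / maxdev)
}
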