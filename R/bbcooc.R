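# Base-bias-corrected co-occurrence (BBC-COOC).
#
# The GC contents of the two intronic windows flanking an exon are
# strongly correlated (GC isochores), which inflates naive
# co-occurrence counts for any pair of same-composition motifs.  The
# correction stratifies exons into an equal-occupancy GC grid,
# accumulates the null expectation of each ordered motif pair across
# the grid, adjusts one hypergeometric margin so the distribution's
# mean equals that expectation, and computes exact tail probabilities.

#' Equal-occupancy GC grid
#'
#' Exons are ranked twice: into `n_bins` rows by the GC content of
#' their upstream window and, independently, into `n_bins` columns by
#' the GC content of their downstream window.  Bin limits are set so
#' that every row and every column holds the same number of exons
#' (within one when `N` is not divisible by `n_bins`).  Ties are
#' broken by a stable sort on (GC, exon_id).
#'
#' @param corpus an [exon_corpus()] whose windows are N-free.
#' @param pairing a [region_pairing()].
#' @param n_bins bins per side (default 20, giving a 20 x 20 grid).
#' @return object of class `gc_grid`: per-exon `row` / `col`
#'   assignments, occupancy matrix `K` (rows = upstream strata,
#'   columns = downstream strata), `row_sizes`, `col_sizes`, `N`.
#' @export
gc_grid <- function(corpus, pairing, n_bins = 20L) {
  up <- extract_region(corpus, pairing$upstream)
  dn <- extract_region(corpus, pairing$downstream)
  if (any(.has_ambiguous(up)) || any(.has_ambiguous(dn)))
    stop("windows contain ambiguous bases; drop those exons first")
  N <- length(up)
  if (N < n_bins) stop("fewer exons (", N, ") than bins (", n_bins, ")")
  gcu <- gc_content(up)
  gcd <- gc_content(dn)
  assign_bins <- function(gc) {
    sizes <- rep(N %/% n_bins, n_bins)
    extra <- N %% n_bins
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    bin <- integer(N)
    bin[order(gc, corpus$exon_id)] <- rep.int(seq_len(n_bins), sizes)
    list(bin = bin, sizes = sizes)
  }
  r <- assign_bins(gcu)
  cl <- assign_bins(gcd)
  K <- matrix(0L, n_bins, n_bins)
  tb <- table(factor(r$bin, seq_len(n_bins)), factor(cl$bin, seq_len(n_bins)))
  K[] <- as.integer(tb)
  structure(list(n_bins = as.integer(n_bins), N = N,
                 row = r$bin, col = cl$bin, K = K,
                 row_sizes = r$sizes, col_sizes = cl$sizes,
                 gc_up = gcu, gc_down = gcd),
            class = "gc_grid")
}

#' @export
print.gc_grid <- function(x, ...) {
  cat(sprintf("<gc_grid> %d x %d, N = %d (row occupancy %d-%d)\n",
              x$n_bins, x$n_bins, x$N, min(x$row_sizes), max(x$row_sizes)))
  invisible(x)
}

#' Per-stratum motif presence table
#'
#' Presence is binary per exon and window: an exon counts once for a
#' motif however many times the motif occurs in its window.  For each
#' of the `4^k` motifs the table holds the number of carrier exons in
#' every stratum (grid row for an upstream window, grid column for a
#' downstream one) and the per-stratum carrier frequency
#' `q = M / stratum size`.
#'
#' @param corpus the corpus the grid was built on.
#' @param grid a [gc_grid()].
#' @param spec the [region_spec()] to scan.
#' @param k motif length (>= 1).
#' @return object of class `presence_table`: `M` (`n_bins x 4^k`
#'   counts), `q` (frequencies), `n` (per-motif carrier totals), `k`,
#'   `side`.
#' @export
presence_table <- function(corpus, grid, spec, k) {
  if (k < 1) stop("k must be >= 1")
  seqs <- extract_region(corpus, spec)
  if (length(seqs) != grid$N) stop("grid was built on a different corpus")
  P <- .presence_matrix(seqs, k)
  stratum <- if (spec$side == "upstream") grid$row else grid$col
  sizes <- if (spec$side == "upstream") grid$row_sizes else grid$col_sizes
  Ind <- Matrix::sparseMatrix(i = seq_len(grid$N), j = stratum, x = 1,
                              dims = c(grid$N, grid$n_bins))
  M <- as.matrix(Matrix::crossprod(Ind, P))
  structure(list(M = M, q = M / sizes, n = Matrix::colSums(P),
                 k = as.integer(k), side = spec$side,
                 sizes = sizes, presence = P),
            class = "presence_table")
}

#' Corrected expected co-occurrence count
#'
#' Under the null hypothesis that carrying the upstream motif is
#' independent of carrying the downstream motif \emph{given} GC
#' stratum, the expected number of exons carrying both in the box at
#' (row y, column x) is `K[y,x] * qU[y] * qD[x]`; the total corrected
#' expectation `k'` sums this over the grid.
#'
#' @param grid a [gc_grid()].
#' @param qU per-row carrier frequencies of the upstream motif
#'   (vector of length `n_bins`, or an `n_bins x m` matrix for many
#'   motifs).
#' @param qD per-column carrier frequencies of the downstream motif
#'   (same shape rules).
#' @return scalar `k'` for vector input; an `m x m'` matrix of
#'   expectations for matrix input.
#' @export
expected_pair_count <- function(grid, qU, qD) {
  if (is.matrix(qU) || is.matrix(qD)) {
    qU <- as.matrix(qU); qD <- as.matrix(qD)
    stopifnot(nrow(qU) == grid$n_bins, nrow(qD) == grid$n_bins)
    return(crossprod(qU, grid$K %*% qD))
  }
  stopifnot(length(qU) == grid$n_bins, length(qD) == grid$n_bins)
  drop(qU %*% grid$K %*% qD)
}

#' Margin adjustment
#'
#' The hypergeometric mean with margins `(N, n_Ui, n_Dj)` is
#' `n_Ui * n_Dj / N`; to make it equal the corrected expectation `k'`
#' while keeping `n_Ui`, the downstream margin is replaced by
#' `n'_Dj = round(N * k' / n_Ui)` (round half to even), clamped to
#' \[0, N\].
#'
#' @param N corpus size.
#' @param n_Ui upstream-motif carrier count (kept fixed).
#' @param k_prime corrected expectation from [expected_pair_count()].
#' @return integer adjusted margin(s); `NA` where `n_Ui = 0` (no test
#'   possible; callers record p = 1).
#' @export
adjust_margin <- function(N, n_Ui, k_prime) {
  out <- round(N * k_prime / n_Ui)
  out[n_Ui == 0] <- NA_real_
  pmin(pmax(out, 0), N)
}

#' Exact hypergeometric tail probabilities for one motif pair
#'
#' Under the adjusted null the joint carrier count K follows the
#' hypergeometric pmf
#' `f(k) = choose(n_adj, k) choose(N - n_adj, n_Ui - k) / choose(N, n_Ui)`.
#' `p_upper = P(K >= k_a)` (enrichment) and `p_lower = P(K <= k_a)`
#' (depletion) are exact tail sums; no Poisson or normal approximation
#' is used.  If rounding pushed the observed count outside the
#' distribution's support, the record is flagged and the offending
#' tail is set to the point mass at the support end.
#'
#' @param N corpus size.
#' @param n_Ui upstream margin.
#' @param n_Dj_adj adjusted downstream margin (see [adjust_margin()]).
#' @param k_a observed joint carrier count.
#' @return list with `p_upper`, `p_lower`, `direction` ("enriched"
#'   iff `k_a` exceeds the null mean), `flagged`.  All components have
#'   the common shape of the inputs.
#' @export
pair_pvalue <- function(N, n_Ui, n_Dj_adj, k_a) {
  if (any(n_Dj_adj < 0 | n_Dj_adj > N | n_Ui < 0 | n_Ui > N, na.rm = TRUE))
    stop("invalid hypergeometric margins")
  lo <- pmax(0, n_Ui + n_Dj_adj - N)
  hi <- pmin(n_Ui, n_Dj_adj)
  over <- k_a > hi
  under <- k_a < lo
  kk <- pmin(pmax(k_a, lo), hi)
  p_upper <- stats::phyper(kk - 1, n_Dj_adj, N - n_Dj_adj, n_Ui,
                           lower.tail = FALSE)
  p_lower <- stats::phyper(kk, n_Dj_adj, N - n_Dj_adj, n_Ui)
  if (any(over)) {
    pm <- stats::dhyper(hi, n_Dj_adj, N - n_Dj_adj, n_Ui)
    p_upper[over] <- pm[over]
    p_lower[over] <- 1
  }
  if (any(under)) {
    pm <- stats::dhyper(lo, n_Dj_adj, N - n_Dj_adj, n_Ui)
    p_lower[under] <- pm[under]
    p_upper[under] <- 1
  }
  mean_null <- n_Ui * n_Dj_adj / N
  dir <- ifelse(k_a > mean_null, "enriched", "depleted")
  list(p_upper = p_upper, p_lower = p_lower, direction = dir,
       flagged = over | under)
}

#' Fit the BBC-COOC co-occurrence scan
#'
#' The central fitting function: scans all `4^(2k)` ordered
#' (upstream motif, downstream motif) pairs over the two windows of
#' `pairing`, with the GC-stratified corrected expectation and
#' adjusted-margin exact hypergeometric test.  Significance uses the
#' enrichment (upper) tail only, at the Bonferroni-like fixed cutoff
#' `alpha = 1 / 4^(2k)` by default; the depletion tail is reported but
#' not thresholded.
#'
#' Exons whose windows contain ambiguous bases are dropped from the
#' scan (count reported in the fit).
#'
#' @param corpus a filtered [exon_corpus()] (see [filter_corpus()]).
#' @param pairing a [region_pairing()] (default UpDp).
#' @param k motif length (default 5; pentamer pairs).
#' @param n_bins GC strata per side (default 20).
#' @param alpha per-test significance cutoff; default `4^(-2k)`.
#' @param adjust which margin to rescale toward the corrected
#'   expectation: `"down"` (default, adjust `n_Dj`), `"up"`, or
#'   `"both"`.
#' @return object of class `bbcooc` with components `k`, `alpha`,
#'   `N`, `n_dropped`, `motifs`, margin vectors `n_U` / `n_D`, full
#'   `4^k x 4^k` matrices `k_a`, `k_prime`, `n_adj`, `p_upper`,
#'   `p_lower`, logical `flagged`, the `grid`, and the `significant`
#'   data.frame (one row per pair with `p_upper <= alpha`).
#' @seealso [summary.bbcooc()], [as.data.frame.bbcooc()],
#'   [cross_region_pvalues()], [gc_balanced_shuffle()]
#' @examples
#' sim <- simulate_corpus(n_exons = 400, seed = 1,
#'   planted = list(plant_pair("ACGTA", "TTGCA", f_both = 0.4)))
#' fit <- bbcooc(sim$corpus, k = 3, n_bins = 5)
#' fit
#' @export
bbcooc <- function(corpus, pairing = region_pairing("UpDp"), k = 5L,
                   n_bins = 20L, alpha = NULL,
                   adjust = c("down", "up", "both")) {
  adjust <- match.arg(adjust)
  if (is.character(pairing)) pairing <- region_pairing(pairing)
  if (k < 1) stop("k must be >= 1")
  if (is.null(alpha)) alpha <- 4^(-2 * k)
  if (nrow(corpus) == 0L) stop("empty corpus")

  up <- extract_region(corpus, pairing$upstream)
  dn <- extract_region(corpus, pairing$downstream)
  drop <- .has_ambiguous(up) | .has_ambiguous(dn)
  n_dropped <- sum(drop)
  if (n_dropped) corpus <- corpus[!drop, , drop = FALSE]
  N <- nrow(corpus)
  if (N < n_bins)
    stop("fewer usable exons (", N, ") than GC bins (", n_bins, ")")

  grid <- gc_grid(corpus, pairing, n_bins)
  ptU <- presence_table(corpus, grid, pairing$upstream, k)
  ptD <- presence_table(corpus, grid, pairing$downstream, k)
  n_U <- ptU$n
  n_D <- ptD$n
  k_prime <- expected_pair_count(grid, ptU$q, ptD$q)
  k_a <- as.matrix(Matrix::crossprod(ptU$presence, ptD$presence))

  if (adjust == "down") {
    n_adj <- adjust_margin(N, n_U, k_prime)          # recycles by row
    mU <- matrix(n_U, nrow = 4^k, ncol = 4^k)
    mD <- n_adj
  } else if (adjust == "up") {
    n_adj <- adjust_margin(N, matrix(n_D, 4^k, 4^k, byrow = TRUE), k_prime)
    mU <- n_adj
    mD <- matrix(n_D, nrow = 4^k, ncol = 4^k, byrow = TRUE)
  } else {
    nn <- outer(n_U, n_D)
    f <- sqrt(N * k_prime / nn)
    f[nn == 0] <- NA_real_
    mU <- pmin(pmax(round(n_U * f), 0), N)
    mD <- pmin(pmax(round(matrix(n_D, 4^k, 4^k, byrow = TRUE) * f), 0), N)
    n_adj <- mD
  }

  skipped <- is.na(mU) | is.na(mD)
  mU[skipped] <- 0; mD[skipped] <- 0
  pv <- pair_pvalue(N, mU, mD, k_a)
  p_upper <- pv$p_upper; p_lower <- pv$p_lower
  p_upper[skipped] <- 1; p_lower[skipped] <- 1

  motifs <- all_kmers(k)
  sig_idx <- which(p_upper <= alpha & !skipped, arr.ind = TRUE)
  significant <- if (nrow(sig_idx) == 0L) data.frame(
    motif_u = character(), motif_d = character(),
    region_pair = character(), N = integer(), n_Ui = integer(),
    n_Dj = integer(), k_prime = numeric(), n_Dj_adj = numeric(),
    k_a = integer(), p_upper = numeric(), p_lower = numeric(),
    significant = logical()) else data.frame(
    motif_u = motifs[sig_idx[, 1L]],
    motif_d = motifs[sig_idx[, 2L]],
    region_pair = pairing$label,
    N = N,
    n_Ui = n_U[sig_idx[, 1L]],
    n_Dj = n_D[sig_idx[, 2L]],
    k_prime = k_prime[sig_idx],
    n_Dj_adj = n_adj[sig_idx],
    k_a = k_a[sig_idx],
    p_upper = p_upper[sig_idx],
    p_lower = p_lower[sig_idx],
    significant = TRUE)
  significant <- significant[order(significant$p_upper), , drop = FALSE]
  rownames(significant) <- NULL

  structure(list(call = match.call(), pairing = pairing, k = as.integer(k),
                 alpha = alpha, n_bins = as.integer(n_bins), N = N,
                 n_dropped = n_dropped, adjust = adjust, motifs = motifs,
                 n_U = n_U, n_D = n_D, k_a = k_a, k_prime = k_prime,
                 n_adj = n_adj, p_upper = p_upper, p_lower = p_lower,
                 flagged = pv$flagged, skipped = skipped, grid = grid,
                 significant = significant),
            class = "bbcooc")
}

#' @export
print.bbcooc <- function(x, ...) {
  cat("Base-bias-corrected co-occurrence scan\n")
  cat(sprintf("  regions: %s   k = %d (%s hypotheses)   grid %d x %d\n",
              x$pairing$label, x$k,
              format(4^(2 * x$k), big.mark = ","), x$n_bins, x$n_bins))
  cat(sprintf("  N = %s exons (%d dropped for ambiguous windows)\n",
              format(x$N, big.mark = ","), x$n_dropped))
  cat(sprintf("  significant pairs at alpha = %.3g: %d\n",
              x$alpha, nrow(x$significant)))
  if (nrow(x$significant)) {
    cat("  top pairs:\n")
    top <- utils::head(x$significant, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s / %s  k_a = %d  k' = %.2f  p = %.3g\n",
                  top$motif_u[i], top$motif_d[i], top$k_a[i],
                  top$k_prime[i], top$p_upper[i]))
  }
  invisible(x)
}

#' Summary of a BBC-COOC fit
#'
#' @param object a `bbcooc` fit.
#' @param ... unused.
#' @return list of class `summary.bbcooc` with hypothesis counts,
#'   p-value calibration quantiles and the significant table.
#' @export
summary.bbcooc <- function(object, ...) {
  p <- object$p_upper[!object$skipped]
  structure(list(
    pairing = object$pairing$label, k = object$k, alpha = object$alpha,
    N = object$N, n_hypotheses = 4^(2 * object$k),
    n_tested = sum(!object$skipped), n_skipped = sum(object$skipped),
    n_flagged = sum(object$flagged & !object$skipped),
    n_significant = nrow(object$significant),
    expected_null = object$alpha * sum(!object$skipped),
    p_quantiles = stats::quantile(p, c(0.01, 0.1, 0.5, 0.9)),
    significant = object$significant),
    class = "summary.bbcooc")
}

#' @export
print.summary.bbcooc <- function(x, ...) {
  cat(sprintf("BBC-COOC %s, k = %d: %d / %s pairs significant at %.3g\n",
              x$pairing, x$k, x$n_significant,
              format(x$n_hypotheses, big.mark = ","), x$alpha))
  cat(sprintf("  N = %s; tested %s, skipped %d, flagged %d\n",
              format(x$N, big.mark = ","),
              format(x$n_tested, big.mark = ","), x$n_skipped, x$n_flagged))
  cat(sprintf("  expected significant under the null: %.2f\n",
              x$expected_null))
  cat("  upper-tail p quantiles:\n")
  print(signif(x$p_quantiles, 3))
  invisible(x)
}

#' Coerce a fit to the tabular result format
#'
#' @param x a `bbcooc` fit.
#' @param row.names,optional ignored (data.frame method signature).
#' @param all return all `4^(2k)` pairs (`TRUE`) or the significant
#'   ones only (default).
#' @param ... unused.
#' @return data.frame with columns `motif_u`, `motif_d`,
#'   `region_pair`, `N`, `n_Ui`, `n_Dj`, `k_prime`, `n_Dj_adj`, `k_a`,
#'   `p_upper`, `p_lower`, `significant`.
#' @export
as.data.frame.bbcooc <- function(x, row.names = NULL, optional = FALSE,
                                 all = FALSE, ...) {
  if (!all) return(x$significant)
  m <- 4^x$k
  u <- rep(seq_len(m), times = m)
  d <- rep(seq_len(m), each = m)
  data.frame(
    motif_u = x$motifs[u], motif_d = x$motifs[d],
    region_pair = x$pairing$label, N = x$N,
    n_Ui = x$n_U[u], n_Dj = x$n_D[d],
    k_prime = as.vector(x$k_prime), n_Dj_adj = as.vector(x$n_adj),
    k_a = as.vector(x$k_a), p_upper = as.vector(x$p_upper),
    p_lower = as.vector(x$p_lower),
    significant = as.vector(x$p_upper <= x$alpha & !x$skipped))
}

#' Diagnostic plot: null calibration of upper-tail p-values
#'
#' Quantile-quantile plot of the observed upper-tail p-values against
#' the uniform distribution (log scale); points far above the
#' diagonal at the small end are the enriched pairs.
#'
#' @param x a `bbcooc` fit.
#' @param max_points subsample cap for plotting.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bbcooc <- function(x, max_points = 20000L, ...) {
  p <- sort(as.vector(x$p_upper[!x$skipped]))
  n <- length(p)
  idx <- if (n > max_points)
    unique(round(exp(seq(0, log(n), length.out = max_points)))) else
      seq_len(n)
  expected <- idx / (n + 1)
  graphics::plot(-log10(expected), -log10(p[idx]),
                 xlab = "-log10 expected p", ylab = "-log10 observed p",
                 main = sprintf("BBC-COOC %s (k = %d)",
                                x$pairing$label, x$k), ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Evaluate discovered pairs in the other regional combinations
#'
#' A pair discovered in one window pairing is regionally specific
#' when it is not significant in the other pairings.  For every
#' significant pair of `fit`, this reruns the scan in each pairing of
#' `others` and reports the pair's upper-tail p-value there, together
#' with a comparability flag marking whether the null expected count
#' in the other pairing is within a factor of two of the defining
#' pairing's (so that similar statistical power can be assumed).
#'
#' @param fit a `bbcooc` fit with at least one significant pair.
#' @param corpus the corpus the fit was computed on.
#' @param others list of [region_pairing()] objects (or labels).
#' @return data.frame with one row per (pair, other pairing):
#'   `motif_u`, `motif_d`, `region_pair`, `p_upper`, `k_prime`,
#'   `expected_within_2x`.
#' @export
cross_region_pvalues <- function(fit, corpus, others) {
  stopifnot(inherits(fit, "bbcooc"))
  sig <- fit$significant
  if (!nrow(sig)) return(data.frame())
  iu <- .kmer_index(sig$motif_u)
  id <- .kmer_index(sig$motif_d)
  out <- list()
  for (p in others) {
    if (is.character(p)) p <- region_pairing(p)
    other <- bbcooc(corpus, p, k = fit$k, n_bins = fit$n_bins,
                    alpha = fit$alpha, adjust = fit$adjust)
    kp <- other$k_prime[cbind(iu, id)]
    ratio <- pmax(kp, sig$k_prime) / pmin(kp, sig$k_prime)
    out[[p$label]] <- data.frame(
      motif_u = sig$motif_u, motif_d = sig$motif_d,
      region_pair = p$label,
      p_upper = other$p_upper[cbind(iu, id)],
      k_prime = kp,
      expected_within_2x = is.finite(ratio) & ratio <= 2)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
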