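# Negative controls and placement scans: the GC-balanced shuffle that
# destroys cross-flank pairing while preserving every single-region
# statistic, the distance scan of window placement, and positional
# occurrence profiles of discovered motifs.

#' GC-balanced shuffle of scanning windows
#'
#' For each shuffled window, the window sequences are permuted
#' uniformly at random \emph{among exons whose windows have exactly
#' the same integer G+C count}.  The multiset of window sequences —
#' and with it every per-region statistic (GC histogram, motif
#' marginal counts) — is preserved corpus-wide and the GC grid is
#' unchanged; only the joint cross-flank association is destroyed.
#' The permutation may have fixed points.  Windows containing
#' ambiguous bases keep their sequence.
#'
#' @param corpus an [exon_corpus()].
#' @param what a [region_spec()], a list of them, or a
#'   [region_pairing()] (then both of its windows are shuffled).
#' @param seed RNG seed; each window side draws from its own named
#'   substream.
#' @return the corpus with shuffled window contents written back into
#'   the flanks.
#' @export
gc_balanced_shuffle <- function(corpus, what, seed) {
  specs <- if (inherits(what, "region_pairing"))
    list(what$upstream, what$downstream)
  else if (inherits(what, "region_spec")) list(what)
  else what
  for (spec in specs) {
    stopifnot(inherits(spec, "region_spec"))
    rng <- .substream(seed, paste0("shuffle_", spec$side, "_", spec$name))
    region <- extract_region(corpus, spec)
    gc <- .gc_count(region)
    perm <- seq_along(region)
    for (ids in split(which(!is.na(gc)), gc[!is.na(gc)])) {
      if (length(ids) < 2L) next
      perm[ids] <- ids[rng$sample_int(length(ids))]
    }
    corpus <- .write_region(corpus, spec, region[perm])
  }
  corpus
}

# Write window sequences back into the stored flanks.
.write_region <- function(corpus, spec, value) {
  if (spec$side == "upstream") {
    L <- nchar(corpus$up_flank)
    from <- L + spec$start_offset + 1L
    to <- L + spec$end_offset + 1L
    substr(corpus$up_flank, from, to) <- value
  } else {
    substr(corpus$down_flank, spec$start_offset, spec$end_offset) <- value
  }
  corpus
}

#' Significant-pair counts at increasing window distances
#'
#' For each distance `d`, a symmetric window pairing is built —
#' upstream `[-(d+49), -d]`, downstream `[+d, +d+49]` — and the full
#' scan is run.  At the exon border the windows respect the
#' splice-site consensus exclusions: the upstream window never ends
#' later than -15 and the downstream window never starts earlier than
#' +7 (so `d <= 15` upstream reproduces Up and `d <= 7` downstream
#' reproduces Dp).  Distances whose windows exceed the stored flanks
#' are flagged with an `NA` count rather than silently skipped.
#'
#' @param corpus a filtered [exon_corpus()].
#' @param distances integer vector of window start distances (nt).
#' @param k,n_bins,alpha,adjust passed to [bbcooc()].
#' @return data.frame of class `distance_scan`: `distance`,
#'   `up_start`, `up_end`, `down_start`, `down_end`, `n_significant`,
#'   `flagged`.
#' @export
distance_scan <- function(corpus, distances, k = 5L, n_bins = 20L,
                          alpha = NULL, adjust = "down") {
  rows <- lapply(distances, function(d) {
    u_end <- -max(d, 15L)
    u_start <- u_end - 49L
    d_start <- max(d, 7L)
    d_end <- d_start + 49L
    enough <- all(nchar(corpus$up_flank) >= -u_start) &&
      all(nchar(corpus$down_flank) >= d_end)
    n_sig <- NA_integer_
    if (enough) {
      pairing <- region_pairing(
        region_spec(paste0("U", d), "upstream", u_start, u_end),
        region_spec(paste0("D", d), "downstream", d_start, d_end),
        label = paste0("dist", d))
      fit <- bbcooc(corpus, pairing, k = k, n_bins = n_bins,
                    alpha = alpha, adjust = adjust)
      n_sig <- nrow(fit$significant)
    }
    data.frame(distance = d, up_start = u_start, up_end = u_end,
               down_start = d_start, down_end = d_end,
               n_significant = n_sig, flagged = !enough)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(distance = integer(), up_start = integer(),
               up_end = integer(), down_start = integer(),
               down_end = integer(), n_significant = integer(),
               flagged = logical())
  class(out) <- c("distance_scan", "data.frame")
  out
}

#' @export
plot.distance_scan <- function(x, ...) {
  graphics::plot(x$distance, x$n_significant, type = "b",
                 xlab = "window distance from exon border (nt)",
                 ylab = "significant motif pairs", ...)
  invisible(x)
}

#' Positional occurrence profile of discovered motifs
#'
#' Counts every occurrence (not carrier exons) of each significant
#' motif at each start position of the window, with positions
#' numbered from the exon-proximal end: position 1 holds the
#' occurrences whose proximal-most base is the window base closest to
#' the exon.
#'
#' @param fit a `bbcooc` fit.
#' @param corpus the corpus scanned.
#' @param spec which of the fit's two windows to profile (its `side`
#'   picks the upstream or downstream motifs of the significant
#'   pairs).
#' @return matrix of class `positional_profile` (motifs x positions);
#'   row sums equal total occurrence counts.
#' @export
positional_distribution <- function(fit, corpus, spec) {
  stopifnot(inherits(fit, "bbcooc"), inherits(spec, "region_spec"))
  motifs <- unique(if (spec$side == "upstream") fit$significant$motif_u
                   else fit$significant$motif_d)
  width <- spec$end_offset - spec$start_offset + 1L
  npos <- width - fit$k + 1L
  prof <- matrix(0L, length(motifs), npos,
                 dimnames = list(motifs, NULL))
  if (!length(motifs)) {
    class(prof) <- c("positional_profile", class(prof))
    return(prof)
  }
  region <- extract_region(corpus, spec)
  W <- .kmer_codes(region, fit$k)   # npos x N, 5'->3' window positions
  idx <- .kmer_index(motifs)
  for (m in seq_along(motifs)) {
    by_start <- rowSums(W == idx[m], na.rm = TRUE)
    prof[m, ] <- if (spec$side == "upstream") rev(by_start) else by_start
  }
  class(prof) <- c("positional_profile", class(prof))
  prof
}
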