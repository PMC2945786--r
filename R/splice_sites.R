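# Splice-site position weight matrices, consensus-value scoring, and
# pseudo exon / pseudo splice-site construction.
#
# Window conventions (positions relative to the splice site):
#   acceptor: intron -14..-1 plus the first exon base (15 positions,
#             the AG at -2,-1);
#   donor:    last 3 exon bases plus intron +1..+6 (9 positions, the
#             GT at +1,+2).
# These are the standard Shapiro-Senapathy extents, chosen so that the
# default scanning windows (ending at -15 / starting at +7) never
# overlap the consensus.

ACCEPTOR_WIDTH <- 15L
DONOR_WIDTH <- 9L

#' Estimate a splice-site position weight matrix from a corpus
#'
#' Per-position base frequencies are tallied over the corpus'
#' `acceptor_window` or `donor_window` column.  The minimal and
#' maximal attainable raw score sums (`s_min`, `s_max`) are stored for
#' 0-100 consensus-value scaling.
#'
#' @param corpus an [exon_corpus()] carrying the relevant window column.
#' @param site_kind `"acceptor"` or `"donor"`.
#' @param on_ambiguous `"drop"` excludes windows containing non-ACGT
#'   characters; `"error"` refuses them.
#' @return object of class `splice_pwm` with elements `site_kind`,
#'   `freq` (4 x width matrix, columns sum to 1), `s_min`, `s_max`.
#' @export
estimate_pwm <- function(corpus, site_kind = c("acceptor", "donor"),
                         on_ambiguous = c("drop", "error")) {
  site_kind <- match.arg(site_kind)
  on_ambiguous <- match.arg(on_ambiguous)
  col <- paste0(site_kind, "_window")
  if (is.null(corpus[[col]])) stop("corpus has no ", col, " column")
  w <- toupper(corpus[[col]])
  if (length(w) == 0L) stop("empty corpus")
  amb <- .has_ambiguous(w)
  if (any(amb)) {
    if (on_ambiguous == "error")
      stop("ambiguous base in ", col, " of exon(s): ",
           paste(utils::head(corpus$exon_id[amb], 5), collapse = ", "))
    w <- w[!amb]
    if (length(w) == 0L) stop("all windows contain ambiguous bases")
  }
  if (length(unique(nchar(w))) != 1L)
    stop("splice-site windows differ in length")
  B <- .encode_bases(w)
  width <- nrow(B)
  freq <- vapply(seq_len(width), function(i)
    tabulate(B[i, ] + 1L, nbins = 4L) / ncol(B), numeric(4))
  dimnames(freq) <- list(.BASES, NULL)
  # s_min over observed bases only (zero-frequency bases score below
  # the minimum; the cv is clamped at 0 for them)
  structure(list(site_kind = site_kind, freq = freq,
                 width = width,
                 s_min = sum(apply(freq, 2, function(f) min(f[f > 0]))),
                 s_max = sum(apply(freq, 2, max))),
            class = "splice_pwm")
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat(sprintf("<splice_pwm> %s site, %d positions, s range [%.3f, %.3f]\n",
              x$site_kind, x$width, x$s_min, x$s_max))
  invisible(x)
}

#' Consensus value (CV) of splice-site windows
#'
#' The raw score `s` of a window is the sum over positions of the
#' frequency of the observed base; it is rescaled to
#' `cv = 100 * (s - s_min) / (s_max - s_min)` so that the best
#' attainable window scores 100 and the worst window over observed
#' bases 0 (`s_min` sums the per-position minima over bases actually
#' seen in the corpus; windows using a never-observed base clamp at
#' 0, and the result is always within \[0, 100\]).
#'
#' @param window character vector of windows (length must match the
#'   PWM width).
#' @param pwm a `splice_pwm` from [estimate_pwm()].
#' @return numeric vector of consensus values in \[0, 100\].
#' @export
score_splice_site <- function(window, pwm) {
  stopifnot(inherits(pwm, "splice_pwm"))
  w <- toupper(window)
  if (any(nchar(w) != pwm$width))
    stop("window length does not match PWM width (", pwm$width, ")")
  B <- .encode_bases(w)
  if (anyNA(B)) stop("ambiguous base in splice-site window")
  s <- colSums(matrix(pwm$freq[cbind(as.vector(B) + 1L,
                                     rep(seq_len(pwm$width), ncol(B)))],
                      nrow = pwm$width))
  if (pwm$s_max <= pwm$s_min) stop("degenerate PWM: s_min == s_max")
  pmin(pmax(100 * (s - pwm$s_min) / (pwm$s_max - pwm$s_min), 0), 100)
}

#' Pseudo exon predicate
#'
#' A candidate intron-internal segment qualifies as a pseudo exon when
#' its length is between 50 and 250 nt, its acceptor consensus value
#' is at least 75 and its donor consensus value at least 78, it lies
#' at least 100 nt away from the closest real exon, and it is bounded
#' by the canonical AG / GT dinucleotides.  All thresholds are
#' boundary-inclusive.
#'
#' @param exon_length candidate length in nt.
#' @param acceptor_cv,donor_cv consensus values from the corpus PWMs.
#' @param distance_to_real distance (nt, border to border) to the
#'   nearest real exon.
#' @param acceptor_dinuc,donor_dinuc bounding intron dinucleotides.
#' @return logical vector.
#' @export
is_pseudo_exon <- function(exon_length, acceptor_cv, donor_cv,
                           distance_to_real,
                           acceptor_dinuc = "AG", donor_dinuc = "GT") {
  exon_length >= 50 & exon_length <= 250 &
    acceptor_cv >= 75 & donor_cv >= 78 &
    distance_to_real >= 100 &
    toupper(acceptor_dinuc) == "AG" & toupper(donor_dinuc) == "GT"
}

#' Locate pseudo splice sites in an exon's intronic flank
#'
#' Scans the upstream flank for decoy acceptor sites (or the
#' downstream flank for decoy donors) anchored on the canonical
#' dinucleotide (AG / GT), keeping candidates whose consensus value is
#' at least as high as the authentic site's and that lie at least
#' `min_distance` nt away from it.
#'
#' Offsets are splice-site relative: an acceptor candidate at offset
#' `o` (negative) would start its exon at intron position `o`, with
#' the AG at `o-2, o-1`; a donor candidate at offset `o` (positive)
#' would end its exon at `o-1`, with the GT at `o, o+1`.
#'
#' @param exon single-row [exon_corpus()] slice (or a list with the
#'   flank and window fields).
#' @param side `"upstream"` (acceptor search) or `"downstream"`
#'   (donor search).
#' @param pwms list with elements `acceptor` and `donor`
#'   (`splice_pwm` objects).
#' @param min_distance minimal distance (nt) from the authentic site.
#' @return data.frame with columns `offset` and `cv` (possibly empty).
#' @export
find_pseudo_splice_sites <- function(exon, side = c("upstream", "downstream"),
                                     pwms, min_distance = 100L) {
  side <- match.arg(side)
  if (side == "upstream") {
    pwm <- pwms$acceptor
    flank <- toupper(exon$up_flank[[1L]])
    authentic_cv <- score_splice_site(exon$acceptor_window[[1L]], pwm)
    L <- nchar(flank)
    # candidate offsets o in [-(L-14), -min_distance]; window occupies
    # flank chars (L+o-14+1)..(L+o+1) i.e. positions o-14..o
    offs <- seq(-(L - ACCEPTOR_WIDTH + 1L), -min_distance)
    if (length(offs) == 0L || offs[1L] > offs[length(offs)])
      return(data.frame(offset = integer(), cv = numeric()))
    din_at <- L + offs - 1L  # char index of the A of AG (position o-2)
    is_ag <- substr(rep(flank, length(offs)), din_at, din_at + 1L) == "AG"
    offs <- offs[is_ag]
    if (!length(offs)) return(data.frame(offset = integer(), cv = numeric()))
    win <- substring(flank, L + offs - ACCEPTOR_WIDTH + 2L, L + offs + 1L)
  } else {
    pwm <- pwms$donor
    flank <- toupper(exon$down_flank[[1L]])
    authentic_cv <- score_splice_site(exon$donor_window[[1L]], pwm)
    L <- nchar(flank)
    # candidate offsets o in [min_distance, L-5]; window occupies flank
    # chars (o-3)..(o+5), i.e. needs o >= 4
    offs <- seq(max(min_distance, 4L), L - DONOR_WIDTH + 4L)
    if (length(offs) == 0L)
      return(data.frame(offset = integer(), cv = numeric()))
    is_gt <- substr(rep(flank, length(offs)), offs, offs + 1L) == "GT"
    offs <- offs[is_gt]
    if (!length(offs)) return(data.frame(offset = integer(), cv = numeric()))
    win <- substring(flank, offs - 3L, offs + 5L)
  }
  ok <- !.has_ambiguous(win)
  offs <- offs[ok]; win <- win[ok]
  if (!length(offs)) return(data.frame(offset = integer(), cv = numeric()))
  cv <- score_splice_site(win, pwm)
  keep <- cv >= authentic_cv
  data.frame(offset = as.integer(offs[keep]), cv = cv[keep])
}
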