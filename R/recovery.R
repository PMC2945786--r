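# Recovery accounting for planted-pair simulations.  Overwriting a
# motif pair into a fraction of exons also creates genuinely
# co-occurring "derivative" pairs: any motif straddling a planted
# occurrence and its random context (sharing k-1 or fewer bases with
# the planted motif) co-occurs with derivatives of the partner
# through the same jointly-planted exons.  When scoring recovery,
# discoveries are therefore attributed to a planted pair when both
# motifs align to the planted motifs with a sufficient exact ungapped
# overlap; only unattributable discoveries count as false.

#' Maximal exact ungapped overlap of two motifs
#'
#' Over all relative shifts, the longest overlap window on which the
#' two motifs agree exactly (0 when they never agree).
#'
#' @param a,b motif strings.
#' @return integer overlap length.
#' @export
motif_overlap <- function(a, b) {
  ka <- nchar(a); kb <- nchar(b)
  best <- 0L
  for (s in (-kb + 1L):(ka - 1L)) {
    from_a <- max(1L, s + 1L); to_a <- min(ka, s + kb)
    if (to_a < from_a) next
    len <- to_a - from_a + 1L
    if (len <= best) next
    if (substr(a, from_a, to_a) ==
        substr(b, from_a - s, to_a - s)) best <- len
  }
  best
}

#' Attribute discovered pairs to planted pairs
#'
#' A significant pair is attributed to a planted pair when its
#' upstream motif overlaps the planted upstream motif and its
#' downstream motif overlaps the planted downstream motif, each by at
#' least `min_overlap` exactly matching bases (see
#' [motif_overlap()]).  Unattributed discoveries are the false
#' positives of a recovery experiment; recall is the fraction of
#' planted pairs recovered exactly.
#'
#' @param discovered data.frame with `motif_u`, `motif_d` (e.g. a
#'   fit's `significant` table).
#' @param planted data.frame with `motif_u`, `motif_d` of the planted
#'   pairs.
#' @param min_overlap minimal exact overlap per side (default
#'   `k - 2`, i.e. 3 for pentamers: only about 0.2 percent of all
#'   ordered pentamer pairs overlap a given planted pair this much on
#'   both sides, so with a background discovery rate of order one the
#'   chance of misattributing an unrelated discovery is negligible,
#'   while planted-context derivatives overlap by at least k - 2 by
#'   construction).
#' @return list with `recall`, `n_false`, `attributed` (logical per
#'   discovered row), `recovered` (logical per planted row).
#' @export
attribute_discoveries <- function(discovered, planted,
                                  min_overlap = NULL) {
  if (is.null(min_overlap))
    min_overlap <- max(nchar(planted$motif_u[1] %||% "AAAAA") - 2L, 1L)
  attributed <- rep(FALSE, nrow(discovered))
  recovered <- rep(FALSE, nrow(planted))
  for (p in seq_len(nrow(planted))) {
    ou <- vapply(discovered$motif_u, motif_overlap,
                 integer(1), b = planted$motif_u[p])
    od <- vapply(discovered$motif_d, motif_overlap,
                 integer(1), b = planted$motif_d[p])
    hit <- ou >= min_overlap & od >= min_overlap
    attributed <- attributed | hit
    recovered[p] <- any(discovered$motif_u == planted$motif_u[p] &
                          discovered$motif_d == planted$motif_d[p])
  }
  list(recall = if (nrow(planted)) mean(recovered) else NA_real_,
       n_false = sum(!attributed),
       attributed = attributed, recovered = recovered)
}
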