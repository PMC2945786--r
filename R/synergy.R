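# Minigene reporter arithmetic: inclusion/skipping proportions,
# skipping fitness, and the synergy index.

#' Proportion of transcripts including the test exon
#'
#' `I = included / (included + skipped)` in molar quantities;
#' `S = 1 - I` is the skipped proportion.
#'
#' @param included_molar,skipped_molar non-negative molar band
#'   quantities (vectors allowed).
#' @return data.frame with `I` and `S` (exactly `I + S = 1`).
#' @export
proportion_included <- function(included_molar, skipped_molar) {
  if (any(included_molar < 0 | skipped_molar < 0))
    stop("band quantities must be non-negative")
  tot <- included_molar + skipped_molar
  if (any(tot == 0)) stop("included + skipped must be positive")
  I <- included_molar / tot
  data.frame(I = I, S = 1 - I)
}

#' Synergy index of a motif pair insertion
#'
#' Skipping fitness relative to the no-insertion construct is
#' `W_x = S_x / S_0` for x in \{U, D, UD\}; the synergy index is
#' `SI = W_UD - W_U * W_D`.  Negative SI means synergy (the pair
#' suppresses skipping more than multiplicatively), positive SI
#' anti-synergy; `|SI| < tol` is classified as `"none"`.
#'
#' @param S_0 skipped proportion of the no-insertion construct
#'   (must be > 0).
#' @param S_U,S_D,S_UD skipped proportions of the single- and
#'   double-insertion constructs.
#' @param tol classification tolerance band around zero
#'   (default 1e-12).
#' @return list of class `synergy_result`: `S_0`, `S_U`, `S_D`,
#'   `S_UD`, `W_U`, `W_D`, `W_UD`, `SI`, `classification`.
#' @export
synergy_index <- function(S_0, S_U, S_D, S_UD, tol = 1e-12) {
  stopifnot(all(c(S_0, S_U, S_D, S_UD) >= 0),
            all(c(S_0, S_U, S_D, S_UD) <= 1))
  if (any(S_0 == 0)) stop("S_0 = 0: skipping fitness undefined")
  W_U <- S_U / S_0; W_D <- S_D / S_0; W_UD <- S_UD / S_0
  SI <- W_UD - W_U * W_D
  classification <- ifelse(abs(SI) < tol, "none",
                           ifelse(SI < 0, "synergy", "anti-synergy"))
  structure(list(S_0 = S_0, S_U = S_U, S_D = S_D, S_UD = S_UD,
                 W_U = W_U, W_D = W_D, W_UD = W_UD, SI = SI,
                 classification = classification),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  for (i in seq_along(x$SI))
    cat(sprintf("SI = %+.4f (%s): W_U = %.3f, W_D = %.3f, W_UD = %.3f\n",
                x$SI[i], x$classification[i], x$W_U[i], x$W_D[i],
                x$W_UD[i]))
  invisible(x)
}

#' Per-replicate synergy from a reporter measurement table
#'
#' Expects one row per (construct, replicate) with molar band
#' quantities, constructs labelled `"none"` (no insertion), `"U"`,
#' `"D"`, `"UD"`.  The synergy index is computed per transfection
#' replicate (replicates are matched by their `replicate` value
#' across constructs) and summarized as mean and standard error of
#' the mean.
#'
#' @param measurements data.frame with columns `construct`,
#'   `replicate`, `included_molar`, `skipped_molar`.
#' @return list with `per_replicate` (data.frame `replicate`, `SI`,
#'   `classification`), `mean_SI`, `sem_SI`.
#' @export
synergy_from_measurements <- function(measurements) {
  req <- c("construct", "replicate", "included_molar", "skipped_molar")
  if (!all(req %in% names(measurements)))
    stop("measurements need columns: ", paste(req, collapse = ", "))
  S <- proportion_included(measurements$included_molar,
                           measurements$skipped_molar)$S
  reps <- sort(unique(measurements$replicate))
  per <- lapply(reps, function(r) {
    sel <- measurements$replicate == r
    get1 <- function(con) {
      v <- S[sel & measurements$construct == con]
      if (length(v) != 1L)
        stop("replicate ", r, ": need exactly one '", con,
             "' measurement")
      v
    }
    si <- synergy_index(get1("none"), get1("U"), get1("D"), get1("UD"))
    data.frame(replicate = r, SI = si$SI,
               classification = si$classification)
  })
  per <- do.call(rbind, per)
  list(per_replicate = per, mean_SI = mean(per$SI),
       sem_SI = stats::sd(per$SI) / sqrt(nrow(per)))
}
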