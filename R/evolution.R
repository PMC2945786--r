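# Evolutionary support: conservation of motif pairing in ortholog
# flanks, GC-matched non-co-occurring control motifs, and SNP density
# in paired vs lone motif occurrences.

#' Conservation of motif pairing in ortholog flanks
#'
#' A motif is "conserved" for an exon when it occurs \emph{anywhere}
#' within the corresponding window of the ortholog's flank (no
#' alignment is performed).  Pairing conservation in the
#' `up_given_down` direction is, among carrier exons whose downstream
#' motif is conserved, the proportion that also conserved the
#' upstream partner; `down_given_up` conditions the other way.
#' Counts are pooled over all supplied pairs.  When `control_pairs`
#' is given (see [select_control_motifs()]) the same proportions are
#' computed for them and a two-proportion z-test of the difference is
#' reported.
#'
#' @param corpus the human corpus.
#' @param orthologs data.frame with `exon_id`, `up_flank`,
#'   `down_flank` (ortholog flanks, transcript orientation).
#' @param pairs data.frame with `motif_u`, `motif_d`.
#' @param pairing the [region_pairing()] defining the windows.
#' @param direction `"up_given_down"`, `"down_given_up"`, or both.
#' @param control_pairs optional data.frame like `pairs`.
#' @return data.frame of class `conservation_result`: one row per
#'   (direction, group) with `conserved`, `n`, `proportion`, and (per
#'   direction) the `p_value` of the co-occurring vs control
#'   difference.  An empty conditioning event yields `NA` with
#'   `flagged = TRUE`.
#' @export
pairing_conservation <- function(corpus, orthologs, pairs, pairing,
                                 direction = c("up_given_down",
                                               "down_given_up"),
                                 control_pairs = NULL) {
  direction <- match.arg(direction, several.ok = TRUE)
  tally <- function(prs) {
    hit <- list(up_given_down = c(0L, 0L), down_given_up = c(0L, 0L))
    m <- match(corpus$exon_id, orthologs$exon_id)
    keep <- !is.na(m)
    corp <- corpus[keep, , drop = FALSE]
    orth <- orthologs[m[keep], , drop = FALSE]
    long_enough <-
      nchar(orth$up_flank) >= -pairing$upstream$start_offset &
      nchar(orth$down_flank) >= pairing$downstream$end_offset
    corp <- corp[long_enough, , drop = FALSE]
    orth <- orth[long_enough, , drop = FALSE]
    hu <- extract_region(corp, pairing$upstream)
    hd <- extract_region(corp, pairing$downstream)
    ou <- extract_region(orth, pairing$upstream)
    od <- extract_region(orth, pairing$downstream)
    for (r in seq_len(nrow(prs))) {
      mu <- prs$motif_u[r]; md <- prs$motif_d[r]
      carrier <- grepl(mu, hu, fixed = TRUE) & grepl(md, hd, fixed = TRUE)
      if (!any(carrier)) next
      cons_u <- grepl(mu, ou[carrier], fixed = TRUE)
      cons_d <- grepl(md, od[carrier], fixed = TRUE)
      hit$up_given_down <- hit$up_given_down +
        c(sum(cons_d & cons_u), sum(cons_d))
      hit$down_given_up <- hit$down_given_up +
        c(sum(cons_u & cons_d), sum(cons_u))
    }
    hit
  }
  co <- tally(pairs)
  ct <- if (!is.null(control_pairs)) tally(control_pairs)
  rows <- list()
  for (d in direction) {
    p_val <- NA_real_
    if (!is.null(ct) && co[[d]][2L] > 0 && ct[[d]][2L] > 0)
      p_val <- .two_prop_z(co[[d]][1L], co[[d]][2L],
                           ct[[d]][1L], ct[[d]][2L])
    rows[[length(rows) + 1L]] <- data.frame(
      direction = d, group = "co_occurring",
      conserved = co[[d]][1L], n = co[[d]][2L],
      proportion = if (co[[d]][2L] > 0) co[[d]][1L] / co[[d]][2L]
                   else NA_real_,
      flagged = co[[d]][2L] == 0, p_value = p_val)
    if (!is.null(ct))
      rows[[length(rows) + 1L]] <- data.frame(
        direction = d, group = "control",
        conserved = ct[[d]][1L], n = ct[[d]][2L],
        proportion = if (ct[[d]][2L] > 0) ct[[d]][1L] / ct[[d]][2L]
                     else NA_real_,
        flagged = ct[[d]][2L] == 0, p_value = p_val)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("conservation_result", "data.frame")
  out
}

# Plain two-proportion z-test (pooled SE, two-sided, no continuity
# correction).
.two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  2 * stats::pnorm(-abs((p1 - p2) / se))
}

#' Select GC-matched non-co-occurring control motifs
#'
#' For each co-occurring pair and each requested side, draws a
#' control k-mer with the same integer G+C count as the replaced
#' motif whose pairing p-value with the original partner exceeds
#' `p_min` (i.e. a non-co-occurring pair of identical composition).
#' Selection is uniform among qualifiers, seeded; pairs with no
#' qualifying k-mer are dropped and logged.
#'
#' @param fit the full `bbcooc` fit (supplies all pairing p-values).
#' @param pairs data.frame with `motif_u`, `motif_d` (default: the
#'   fit's significant pairs).
#' @param side which motif to replace: `"up"` or `"down"`.
#' @param seed RNG seed.
#' @param p_min candidates must have `p_upper > p_min` (default 0.05).
#' @return data.frame `motif_u`, `motif_d`, `side`, `control_motif`;
#'   dropped pairs recorded in the `dropped` attribute.
#' @export
select_control_motifs <- function(fit, pairs = fit$significant,
                                  side = c("down", "up"), seed = 1L,
                                  p_min = 0.05) {
  side <- match.arg(side)
  rng <- .substream(seed, paste0("control_motifs_", side))
  gc_all <- .gc_count(fit$motifs)
  rows <- list(); dropped <- list()
  for (r in seq_len(nrow(pairs))) {
    iu <- .kmer_index(pairs$motif_u[r])
    id <- .kmer_index(pairs$motif_d[r])
    if (side == "down") {
      cand <- which(gc_all == gc_all[id])
      ok <- cand[fit$p_upper[iu, cand] > p_min & cand != id]
    } else {
      cand <- which(gc_all == gc_all[iu])
      ok <- cand[fit$p_upper[cand, id] > p_min & cand != iu]
    }
    if (!length(ok)) {
      dropped[[length(dropped) + 1L]] <- pairs[r, c("motif_u", "motif_d")]
      next
    }
    pick <- ok[rng$sample_int(length(ok), 1L)]
    rows[[length(rows) + 1L]] <- data.frame(
      motif_u = if (side == "up") fit$motifs[pick] else pairs$motif_u[r],
      motif_d = if (side == "down") fit$motifs[pick] else pairs$motif_d[r],
      side = side, control_motif = fit$motifs[pick])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_u = character(), motif_d = character(),
               side = character(), control_motif = character())
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    NULL
  out
}

#' SNP density in paired vs lone motif occurrences
#'
#' Every occurrence of either motif of each pair within its window is
#' classified as "paired" (the partner motif is present in the
#' partner window of the same exon) or "alone".  An occurrence
#' contains a SNP when any of its k positions carries one.  Reports
#' the proportion of occurrences containing at least one SNP per
#' class, binomial standard errors, and a two-proportion z-test.
#'
#' @param corpus the corpus.
#' @param snps data.frame with `exon_id`, `side` (`"up"` / `"down"`),
#'   `pos` (1-based position within the stored flank string).
#' @param pairs data.frame with `motif_u`, `motif_d`.
#' @param pairing the [region_pairing()].
#' @return list of class `snp_density_result`: `paired` and `alone`
#'   (each `x`, `n`, `proportion`, `se`), `p_value`, `flagged`.
#' @export
snp_motif_density <- function(corpus, snps, pairs, pairing) {
  up <- extract_region(corpus, pairing$upstream)
  dn <- extract_region(corpus, pairing$downstream)
  Lu <- nchar(corpus$up_flank)
  u_from <- Lu + pairing$upstream$start_offset      # 0-based offset base
  d_from <- pairing$downstream$start_offset - 1L
  snp_key <- paste(snps$exon_id, snps$side, snps$pos)
  counts <- c(paired_snp = 0L, paired = 0L, alone_snp = 0L, alone = 0L)
  scan_side <- function(motif, partner, region, partner_region,
                        from0, side_lab) {
    k <- nchar(motif)
    has_partner <- grepl(partner, partner_region, fixed = TRUE)
    hits <- gregexpr(motif, region, fixed = TRUE)
    for (e in seq_along(region)) {
      st <- hits[[e]]
      if (st[1L] == -1L) next
      # all (incl. overlapping) occurrences: rescan shifted suffixes
      st <- .all_starts(region[e], motif)
      for (s in st) {
        flank_pos <- from0[e] + s - 1L + seq_len(k)
        snp_hit <- any(paste(corpus$exon_id[e], side_lab, flank_pos) %in%
                         snp_key)
        cls <- if (has_partner[e]) "paired" else "alone"
        counts[[cls]] <<- counts[[cls]] + 1L
        if (snp_hit) counts[[paste0(cls, "_snp")]] <<-
            counts[[paste0(cls, "_snp")]] + 1L
      }
    }
  }
  for (r in seq_len(nrow(pairs))) {
    scan_side(pairs$motif_u[r], pairs$motif_d[r], up, dn, u_from, "up")
    scan_side(pairs$motif_d[r], pairs$motif_u[r], dn, up,
              rep(d_from, length(dn)), "down")
  }
  prop <- function(x, n) if (n > 0) x / n else NA_real_
  se <- function(x, n) if (n > 0) sqrt(x / n * (1 - x / n) / n) else
    NA_real_
  flagged <- counts[["paired"]] == 0L || counts[["alone"]] == 0L
  p_value <- if (!flagged)
    .two_prop_z(counts[["paired_snp"]], counts[["paired"]],
                counts[["alone_snp"]], counts[["alone"]]) else NA_real_
  structure(list(
    paired = list(x = counts[["paired_snp"]], n = counts[["paired"]],
                  proportion = prop(counts[["paired_snp"]],
                                    counts[["paired"]]),
                  se = se(counts[["paired_snp"]], counts[["paired"]])),
    alone = list(x = counts[["alone_snp"]], n = counts[["alone"]],
                 proportion = prop(counts[["alone_snp"]],
                                   counts[["alone"]]),
                 se = se(counts[["alone_snp"]], counts[["alone"]])),
    p_value = p_value, flagged = flagged),
    class = "snp_density_result")
}

# Start positions of all (overlapping) occurrences of motif in seq.
.all_starts <- function(seq, motif) {
  k <- nchar(motif)
  out <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(motif, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (hit == -1L) break
    out <- c(out, from + hit - 1L)
    from <- from + hit
  }
  out
}
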