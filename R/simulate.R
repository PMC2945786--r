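# Seeded synthetic-corpus generator.  Emulates the statistical
# structure the analyses assume: GC contents of the two flanks of an
# exon correlated through a latent isochore value, splice-site
# windows drawn from a consensus frequency matrix, motif pairs
# planted into defined windows with a truth ledger, plus matching
# ortholog flanks, SNP tables and expression matrices.

# Consensus base frequencies for splice-site window generation
# (acceptor: intron -14..-1 + first exon base; donor: last 3 exon
# bases + intron +1..+6).  The AG / GT dinucleotides are forced to be
# canonical.
.ACCEPTOR_CONS <- local({
  m <- matrix(0.1, 4, 15, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in 1:10) m[, i] <- c(0.08, 0.35, 0.12, 0.45)  # polypyrimidine
  m[, 11] <- c(0.25, 0.30, 0.20, 0.25)
  m[, 12] <- c(0.10, 0.65, 0.05, 0.20)
  m[, 13] <- c(1.00, 0.00, 0.00, 0.00)                 # A of AG
  m[, 14] <- c(0.00, 0.00, 1.00, 0.00)                 # G of AG
  m[, 15] <- c(0.28, 0.14, 0.50, 0.08)                 # first exon base
  m
})

.DONOR_CONS <- local({
  m <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[, 1] <- c(0.33, 0.37, 0.18, 0.12)
  m[, 2] <- c(0.60, 0.13, 0.14, 0.13)
  m[, 3] <- c(0.10, 0.05, 0.80, 0.05)                  # last exon base
  m[, 4] <- c(0.00, 0.00, 1.00, 0.00)                  # G of GT
  m[, 5] <- c(0.00, 0.00, 0.00, 1.00)                  # T of GT
  m[, 6] <- c(0.60, 0.04, 0.30, 0.06)
  m[, 7] <- c(0.70, 0.08, 0.12, 0.10)
  m[, 8] <- c(0.08, 0.06, 0.80, 0.06)
  m[, 9] <- c(0.16, 0.16, 0.20, 0.48)
  m
})

#' Calibrate the isochore spread for a target flank-GC correlation
#'
#' In the generator, the measured GC of a scanning window is
#' `latent isochore + per-flank noise + binomial sampling noise`;
#' the Pearson correlation between the two windows of an exon is
#' `v_iso / (v_iso + v_noise + v_binom)` with
#' `v_binom = gc_mean (1 - gc_mean) / window_length`.  This inverts
#' that relation to obtain the isochore standard deviation hitting a
#' target correlation.
#'
#' @param target_r target Pearson correlation of the two window GCs
#'   (default 0.73, the empirical flank-GC correlation around human
#'   internal exons).
#' @param flank_noise_sd per-flank GC noise sd (default 0.03).
#' @param window_length nt of the window the correlation is measured
#'   on (default 50).
#' @param gc_mean mean GC (default 0.47).
#' @return isochore standard deviation.
#' @export
calibrate_isochore_sd <- function(target_r = 0.73, flank_noise_sd = 0.03,
                                  window_length = 50L, gc_mean = 0.47) {
  stopifnot(target_r > 0, target_r < 1)
  vb <- gc_mean * (1 - gc_mean) / window_length
  sqrt(target_r / (1 - target_r) * (flank_noise_sd^2 + vb))
}

#' Describe a motif pair to plant into a synthetic corpus
#'
#' @param motif_u,motif_d upstream / downstream motifs (uppercase
#'   ACGT, equal length).
#' @param pairing [region_pairing()] or preset label naming the
#'   windows planted into (default `"UpDp"`).
#' @param f_both fraction of exons receiving both motifs jointly.
#' @param f_u,f_d fractions receiving only the upstream / only the
#'   downstream motif (`f_both + f_u <= 1`, `f_both + f_d <= 1`).
#' @param positional_bias optional probability vector over window
#'   start offsets (default uniform).
#' @return list of class `plant_spec`.
#' @export
plant_pair <- function(motif_u, motif_d, pairing = "UpDp", f_both,
                       f_u = 0, f_d = 0, positional_bias = NULL) {
  if (is.character(pairing)) pairing <- region_pairing(pairing)
  motif_u <- toupper(motif_u); motif_d <- toupper(motif_d)
  stopifnot(!grepl("[^ACGT]", motif_u), !grepl("[^ACGT]", motif_d),
            f_both >= 0, f_u >= 0, f_d >= 0,
            f_both + f_u + f_d <= 1)
  structure(list(motif_u = motif_u, motif_d = motif_d, pairing = pairing,
                 f_both = f_both, f_u = f_u, f_d = f_d,
                 positional_bias = positional_bias),
            class = "plant_spec")
}

#' Generate a synthetic exon corpus with a planted-motif truth ledger
#'
#' Per exon, a latent isochore GC value is drawn and each flank's
#' base composition follows it plus independent per-flank noise, so
#' that the GC contents of the two scanning windows are correlated at
#' the calibrated target (see [calibrate_isochore_sd()]).  Bases are
#' drawn independently with `P(G) = P(C) = GC/2`.  Splice-site
#' windows are sampled from consensus frequency matrices softened
#' toward uniform by `site_temperature`, with the canonical AG / GT
#' forced, and are written into the adjacent flank/exon ends.
#' Planted motifs overwrite the sequence at offsets sampled within
#' their window (uniformly unless a positional bias is configured);
#' overlapping plants within one window are re-sampled and skipped
#' when no free offset is found.  Fully deterministic given `seed`:
#' every component draws from its own named substream.
#'
#' @param n_exons number of exons.
#' @param flank_length nt per flank (default 100; increase for
#'   distance scans).
#' @param exon_length exon length (default 120).
#' @param gc_mean mean GC of intronic flanks (default 0.47).
#' @param gc_corr target correlation of the two window GCs
#'   (default 0.73).
#' @param flank_noise_sd per-flank GC noise sd (default 0.03).
#' @param planted list of [plant_pair()] specs.
#' @param site_temperature mix of the splice-site consensus toward
#'   uniform, in \[0, 1\] (default 0.1).
#' @param splice_class class label for the records.
#' @param seed RNG seed.
#' @return list with `corpus` (an [exon_corpus()]) and `truth`
#'   (data.frame `exon_id`, `motif`, `side`, `region`,
#'   `window_offset`, `flank_pos`, `planted_as`).
#' @export
simulate_corpus <- function(n_exons, flank_length = 100L,
                            exon_length = 120L, gc_mean = 0.47,
                            gc_corr = 0.73, flank_noise_sd = 0.03,
                            planted = list(), site_temperature = 0.1,
                            splice_class = "constitutive", seed) {
  stopifnot(n_exons >= 1, flank_length >= 21, exon_length >= 6)
  iso_sd <- calibrate_isochore_sd(gc_corr, flank_noise_sd,
                                  window_length = 50L, gc_mean = gc_mean)
  g <- .substream(seed, "isochore")$rnorm(n_exons, gc_mean, iso_sd)
  clamp <- function(x) pmin(pmax(x, 0.05), 0.95)
  p_up <- clamp(g + .substream(seed, "noise_up")$rnorm(n_exons, 0,
                                                       flank_noise_sd))
  p_dn <- clamp(g + .substream(seed, "noise_dn")$rnorm(n_exons, 0,
                                                       flank_noise_sd))
  up_flank <- .sample_flanks(p_up, flank_length,
                             .substream(seed, "flank_up"))
  down_flank <- .sample_flanks(p_dn, flank_length,
                               .substream(seed, "flank_dn"))
  exon_seq <- .sample_flanks(rep(0.5, n_exons), exon_length,
                             .substream(seed, "exon"))

  acc <- .sample_sites(.ACCEPTOR_CONS, site_temperature, n_exons,
                       .substream(seed, "acceptor"))
  don <- .sample_sites(.DONOR_CONS, site_temperature, n_exons,
                       .substream(seed, "donor"))
  # weld the site windows onto the adjacent sequence ends
  substr(up_flank, flank_length - 13L, flank_length) <- substr(acc, 1, 14)
  substr(exon_seq, 1L, 1L) <- substr(acc, 15, 15)
  substr(exon_seq, exon_length - 2L, exon_length) <- substr(don, 1, 3)
  substr(down_flank, 1L, 6L) <- substr(don, 4, 9)

  exon_id <- sprintf("ex%06d", seq_len(n_exons))
  corpus <- data.frame(exon_id = exon_id,
                       gene_id = sprintf("g%06d", seq_len(n_exons)),
                       splice_class = splice_class,
                       exon_seq = exon_seq, up_flank = up_flank,
                       down_flank = down_flank,
                       acceptor_window = acc, donor_window = don)

  truth <- list()
  occupied <- list(up = vector("list", n_exons),
                   dn = vector("list", n_exons))
  for (ps in planted) {
    stopifnot(inherits(ps, "plant_spec"))
    assign_rng <- .substream(seed, paste0("assign_", ps$motif_u, "_",
                                          ps$motif_d))
    off_rng <- .substream(seed, paste0("offset_", ps$motif_u, "_",
                                       ps$motif_d))
    u <- assign_rng$runif(n_exons)
    both <- u < ps$f_both
    uonly <- !both & u < ps$f_both + ps$f_u
    donly <- !both & !uonly & u < ps$f_both + ps$f_u + ps$f_d
    for (side in c("up", "dn")) {
      motif <- if (side == "up") ps$motif_u else ps$motif_d
      spec <- if (side == "up") ps$pairing$upstream else
        ps$pairing$downstream
      who <- which(both | (if (side == "up") uonly else donly))
      if (!length(who)) next
      W <- spec$end_offset - spec$start_offset + 1L
      k <- nchar(motif)
      if (k > W) stop("motif longer than its window")
      npos <- W - k + 1L
      probs <- ps$positional_bias %||% rep(1 / npos, npos)
      res <- .plant_into(corpus, occupied, side, spec, motif, who,
                         probs, off_rng, flank_length)
      corpus <- res$corpus; occupied <- res$occupied
      if (nrow(res$ledger)) {
        res$ledger$planted_as <- ifelse(both[match(res$ledger$exon_id,
                                                   exon_id)],
                                        "pair", "single")
        truth[[length(truth) + 1L]] <- res$ledger
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(exon_id = character(), motif = character(),
               side = character(), region = character(),
               window_offset = integer(), flank_pos = integer(),
               planted_as = character())
  rownames(truth) <- NULL
  list(corpus = exon_corpus(corpus), truth = truth)
}

# Sample n flank strings of length L, column GC targets p.
.sample_flanks <- function(p, L, rng) {
  n <- length(p)
  is_gc <- rng$runif(L * n) < rep(p, each = L)
  half <- rng$runif(L * n) < 0.5
  code <- ifelse(is_gc, ifelse(half, 71L, 67L),   # G / C
                 ifelse(half, 65L, 84L))          # A / T
  m <- matrix(code, nrow = L)
  vapply(seq_len(n), function(j) intToUtf8(m[, j]), character(1))
}

# Sample splice-site windows from a consensus matrix softened toward
# uniform; positions with a fixed base (freq 1) stay fixed.
.sample_sites <- function(cons, temperature, n, rng) {
  W <- ncol(cons)
  freq <- (1 - temperature) * cons + temperature * 0.25
  freq[, apply(cons == 1, 2, any)] <- cons[, apply(cons == 1, 2, any)]
  out <- matrix(0L, W, n)
  for (i in seq_len(W)) {
    cum <- cumsum(freq[, i])
    u <- rng$runif(n)
    out[i, ] <- utf8ToInt("ACGT")[pmin(findInterval(u, cum) + 1L, 4L)]
  }
  vapply(seq_len(n), function(j) intToUtf8(out[, j]), character(1))
}

# Overwrite `motif` into the window of `spec` for exons `who`,
# avoiding previously planted intervals (up to 20 resamples each).
.plant_into <- function(corpus, occupied, side, spec, motif, who, probs,
                        rng, flank_length) {
  k <- nchar(motif)
  npos <- length(probs)
  ledger <- list()
  occ_key <- side
  for (e in who) {
    taken <- occupied[[occ_key]][[e]]
    off <- NA_integer_
    for (try in 1:20) {
      cand <- min(findInterval(rng$runif(1), cumsum(probs)) + 1L, npos)
      span <- cand:(cand + k - 1L)
      if (!length(taken) || !any(span %in% taken)) { off <- cand; break }
    }
    if (is.na(off)) next
    if (spec$side == "upstream") {
      from <- flank_length + spec$start_offset + off
      substr(corpus$up_flank[e], from, from + k - 1L) <- motif
    } else {
      from <- spec$start_offset + off - 1L
      substr(corpus$down_flank[e], from, from + k - 1L) <- motif
    }
    occupied[[occ_key]][[e]] <- c(taken, off:(off + k - 1L))
    ledger[[length(ledger) + 1L]] <- data.frame(
      exon_id = corpus$exon_id[e], motif = motif,
      side = if (spec$side == "upstream") "up" else "down",
      region = spec$name, window_offset = off, flank_pos = from)
  }
  list(corpus = corpus, occupied = occupied,
       ledger = if (length(ledger)) do.call(rbind, ledger) else
         data.frame(exon_id = character(), motif = character(),
                    side = character(), region = character(),
                    window_offset = integer(), flank_pos = integer()))
}

#' Generate ortholog flanks by neutral substitution with motif
#' retention
#'
#' Each flank base is substituted with probability `mu` (to a
#' different base, uniformly).  Every planted motif is retained
#' intact with probability `rho_pair` (when planted as a pair) or
#' `rho_single` (when planted alone); a non-retained motif is
#' mutated like background.
#'
#' @param corpus,truth output of [simulate_corpus()].
#' @param mu per-base substitution rate in \[0, 1\].
#' @param rho_pair,rho_single motif retention probabilities.
#' @param seed RNG seed.
#' @return data.frame `exon_id`, `up_flank`, `down_flank`.
#' @export
generate_orthologs <- function(corpus, truth, mu, rho_pair, rho_single,
                               seed) {
  stopifnot(mu >= 0, mu <= 1, rho_pair >= 0, rho_pair <= 1,
            rho_single >= 0, rho_single <= 1)
  mut_rng <- .substream(seed, "ortholog_mutation")
  ret_rng <- .substream(seed, "ortholog_retention")
  mutate <- function(seqs) {
    n <- length(seqs); L <- nchar(seqs[1L])
    codes <- .encode_bases(seqs)
    hit <- matrix(mut_rng$runif(L * n) < mu, L, n)
    u <- mut_rng$runif(L * n)
    # shift in {1,2,3}: adding mod 4 always lands on a different base
    shift <- matrix(1L + (u >= 1 / 3) + (u >= 2 / 3), L, n)
    codes[hit] <- (codes[hit] + shift[hit]) %% 4L
    m <- matrix(utf8ToInt("ACGT")[codes + 1L], L, n)
    vapply(seq_len(n), function(j) intToUtf8(m[, j]), character(1))
  }
  up <- mutate(corpus$up_flank)
  dn <- mutate(corpus$down_flank)
  if (nrow(truth)) {
    rho <- ifelse(truth$planted_as == "pair", rho_pair, rho_single)
    keep <- ret_rng$runif(nrow(truth)) < rho
    for (i in which(keep)) {
      e <- match(truth$exon_id[i], corpus$exon_id)
      k <- nchar(truth$motif[i])
      if (truth$side[i] == "up")
        substr(up[e], truth$flank_pos[i],
               truth$flank_pos[i] + k - 1L) <- truth$motif[i]
      else
        substr(dn[e], truth$flank_pos[i],
               truth$flank_pos[i] + k - 1L) <- truth$motif[i]
    }
  }
  data.frame(exon_id = corpus$exon_id, up_flank = up, down_flank = dn)
}

#' Simulate a SNP table over the corpus flanks
#'
#' Each flank base carries a SNP independently at `base_rate`,
#' multiplied by `paired_multiplier` at positions inside motifs
#' planted as a pair.
#'
#' @param corpus,truth output of [simulate_corpus()].
#' @param base_rate per-base SNP probability.
#' @param paired_multiplier rate multiplier inside pair-planted
#'   motifs (e.g. 0.5 for purifying selection on functional pairs).
#' @param seed RNG seed.
#' @return data.frame `exon_id`, `side`, `pos` (1-based flank
#'   position).
#' @export
generate_snps <- function(corpus, truth, base_rate,
                          paired_multiplier = 1, seed) {
  stopifnot(base_rate >= 0, base_rate <= 1, paired_multiplier >= 0)
  rng <- .substream(seed, "snps")
  n <- nrow(corpus)
  out <- list()
  for (side in c("up", "down")) {
    L <- nchar(if (side == "up") corpus$up_flank else
      corpus$down_flank)[1L]
    rate <- matrix(base_rate, L, n)
    tr <- truth[truth$side == side & truth$planted_as == "pair", ,
                drop = FALSE]
    if (nrow(tr)) {
      e <- match(tr$exon_id, corpus$exon_id)
      for (i in seq_len(nrow(tr))) {
        span <- tr$flank_pos[i]:(tr$flank_pos[i] + nchar(tr$motif[i]) - 1L)
        rate[span, e[i]] <- base_rate * paired_multiplier
      }
    }
    hit <- matrix(rng$runif(L * n), L, n) < rate
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx))
      out[[side]] <- data.frame(exon_id = corpus$exon_id[idx[, 2L]],
                                side = side, pos = idx[, 1L])
  }
  if (!length(out))
    return(data.frame(exon_id = character(), side = character(),
                      pos = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a genes x tissues expression matrix
#'
#' Baseline expression is log-normal per gene across tissues;
#' designated (gene, tissue) cells are then raised to the gene's
#' baseline median plus `effect_sd` baseline standard deviations,
#' making them recoverable by [tissue_specific_sets()] when
#' `effect_sd > 2`.
#'
#' @param genes gene names (or a count).
#' @param tissues tissue names (or a count; default 79).
#' @param specific data.frame with `gene`, `tissue` naming the
#'   planted tissue-specific cells (`NULL` for none).
#' @param effect_sd boost in baseline standard deviations
#'   (default 5).
#' @param seed RNG seed.
#' @return numeric matrix with dimnames.
#' @export
generate_expression <- function(genes, tissues = 79L, specific = NULL,
                                effect_sd = 5, seed) {
  if (is.numeric(genes)) genes <- sprintf("g%05d", seq_len(genes))
  if (is.numeric(tissues)) tissues <- sprintf("tissue%02d",
                                              seq_len(tissues))
  rng <- .substream(seed, "expression")
  ng <- length(genes); nt <- length(tissues)
  base_mean <- rng$rnorm(ng, 6, 1)
  expr <- matrix(exp(rng$rnorm(ng * nt, rep(base_mean, nt), 0.4)),
                 ng, nt, dimnames = list(genes, tissues))
  if (!is.null(specific) && nrow(specific)) {
    med <- apply(expr, 1L, stats::median)
    sdv <- apply(expr, 1L, stats::sd)
    gi <- match(specific$gene, genes)
    ti <- match(specific$tissue, tissues)
    if (anyNA(gi) || anyNA(ti)) stop("unknown gene/tissue in `specific`")
    expr[cbind(gi, ti)] <- med[gi] + effect_sd * sdv[gi]
  }
  expr
}
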