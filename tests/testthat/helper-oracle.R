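# Independent oracles: a naive loop-and-choose reimplementation of
# the co-occurrence scan, used to validate the vectorized path, plus
# small fixture builders.

# Hypergeometric pmf from first principles (choose() only).
oracle_hyper_pmf <- function(k, N, nU, nD) {
  choose(nD, k) * choose(N - nD, nU - k) / choose(N, nU)
}

oracle_tails <- function(k_a, N, nU, nD) {
  lo <- max(0, nU + nD - N)
  hi <- min(nU, nD)
  list(p_upper = sum(oracle_hyper_pmf(k_a:hi, N, nU, nD)),
       p_lower = sum(oracle_hyper_pmf(lo:k_a, N, nU, nD)))
}

# Naive scan: string matching with grepl, explicit per-bin loops, no
# sparse algebra.  Same definitions (equal-occupancy grid, binary
# presence, corrected expectation, rounded margin, exact tails).
oracle_scan <- function(corpus, pairing, k, n_bins, alpha = 4^(-2 * k)) {
  up <- extract_region(corpus, pairing$upstream)
  dn <- extract_region(corpus, pairing$downstream)
  N <- length(up)
  gc_of <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch %in% c("G", "C")) / length(ch)
  }
  gcu <- vapply(up, gc_of, numeric(1))
  gcd <- vapply(dn, gc_of, numeric(1))
  bin_of <- function(gc) {
    sizes <- rep(N %/% n_bins, n_bins)
    if (N %% n_bins) sizes[seq_len(N %% n_bins)] <-
        sizes[seq_len(N %% n_bins)] + 1L
    b <- integer(N)
    b[order(gc, corpus$exon_id)] <- rep(seq_len(n_bins), sizes)
    list(b = b, sizes = sizes)
  }
  rw <- bin_of(gcu); cl <- bin_of(gcd)
  motifs <- all_kmers(k)
  m <- length(motifs)
  presU <- sapply(motifs, function(mm) grepl(mm, up, fixed = TRUE))
  presD <- sapply(motifs, function(mm) grepl(mm, dn, fixed = TRUE))
  K <- matrix(0, n_bins, n_bins)
  for (e in seq_len(N)) K[rw$b[e], cl$b[e]] <- K[rw$b[e], cl$b[e]] + 1
  out <- expand.grid(u = seq_len(m), d = seq_len(m))
  out$n_Ui <- colSums(presU)[out$u]
  out$n_Dj <- colSums(presD)[out$d]
  res <- lapply(seq_len(nrow(out)), function(r) {
    u <- out$u[r]; d <- out$d[r]
    kp <- 0
    for (y in seq_len(n_bins)) for (x in seq_len(n_bins)) {
      qU <- sum(presU[rw$b == y, u]) / rw$sizes[y]
      qD <- sum(presD[cl$b == x, d]) / cl$sizes[x]
      kp <- kp + K[y, x] * qU * qD
    }
    nU <- out$n_Ui[r]
    ka <- sum(presU[, u] & presD[, d])
    if (nU == 0) return(c(kp, NA, ka, 1, 1))
    nadj <- min(max(round(N * kp / nU), 0), N)
    lo <- max(0, nU + nadj - N); hi <- min(nU, nadj)
    kk <- min(max(ka, lo), hi)
    t <- oracle_tails(kk, N, nU, nadj)
    pu <- t$p_upper; pl <- t$p_lower
    if (ka > hi) { pu <- oracle_hyper_pmf(hi, N, nU, nadj); pl <- 1 }
    if (ka < lo) { pl <- oracle_hyper_pmf(lo, N, nU, nadj); pu <- 1 }
    c(kp, nadj, ka, pu, pl)
  })
  res <- do.call(rbind, res)
  out$k_prime <- res[, 1]; out$n_adj <- res[, 2]; out$k_a <- res[, 3]
  out$p_upper <- res[, 4]; out$p_lower <- res[, 5]
  out$motif_u <- motifs[out$u]; out$motif_d <- motifs[out$d]
  out
}

# A deterministic toy corpus with hand-controllable windows: flanks
# are random but reproducible, 100 nt each.
toy_corpus <- function(n, seed = 42, flank = 100, exon = 60) {
  set.seed(seed)
  rnd <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                  replace = TRUE), collapse = "")
  exon_corpus(data.frame(
    exon_id = sprintf("t%03d", seq_len(n)),
    gene_id = sprintf("g%03d", seq_len(n)),
    splice_class = "constitutive",
    exon_seq = vapply(seq_len(n), function(i) rnd(exon), character(1)),
    up_flank = vapply(seq_len(n), function(i) rnd(flank), character(1)),
    down_flank = vapply(seq_len(n), function(i) rnd(flank),
                        character(1))))
}
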