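test_that("gc_grid balances row and column occupancy", {
  corp <- toy_corpus(40)
  g <- gc_grid(corp, region_pairing("UpDp"), n_bins = 20)
  expect_equal(g$row_sizes, rep(2L, 20))
  expect_equal(g$col_sizes, rep(2L, 20))
  expect_equal(sum(g$K), 40)
  expect_equal(tabulate(g$row, 20), rep(2L, 20))
  # N not divisible by n_bins: occupancy within one
  g2 <- gc_grid(toy_corpus(43), region_pairing("UpDp"), n_bins = 20)
  expect_true(all(abs(g2$row_sizes - 43 / 20) < 1))
  expect_equal(sum(g2$row_sizes), 43)
  # ties: identical GC everywhere still balances deterministically
  corp3 <- toy_corpus(30)
  corp3$up_flank <- rep(corp3$up_flank[1], 30)
  corp3$down_flank <- rep(corp3$down_flank[1], 30)
  g3a <- gc_grid(corp3, region_pairing("UpDp"), n_bins = 5)
  g3b <- gc_grid(corp3, region_pairing("UpDp"), n_bins = 5)
  expect_equal(tabulate(g3a$row, 5), rep(6L, 5))
  expect_identical(g3a$row, g3b$row)
  # degenerate single box
  g4 <- gc_grid(corp, region_pairing("UpDp"), n_bins = 1)
  expect_equal(g4$K, matrix(40L, 1, 1))
  expect_error(gc_grid(toy_corpus(5), region_pairing("UpDp"), 20),
               "fewer exons")
})

test_that("presence is binary per exon-region and sums per stratum", {
  corp <- toy_corpus(4)
  L <- nchar(corp$up_flank[1])
  # poly-A window: 46 occurrences of AAAAA but one carrier
  substr(corp$up_flank[1], L - 64 + 1, L - 15 + 1) <-
    paste(rep("A", 50), collapse = "")
  g <- gc_grid(corp, region_pairing("UpDp"), n_bins = 2)
  pt <- presence_table(corp, g, region_presets()$Up, k = 5)
  i <- match("AAAAA", all_kmers(5))
  expect_equal(pt$n[[i]], 1)
  expect_equal(sum(pt$M[, i]), 1)
  # per-motif stratum counts always reconstitute the margin
  expect_equal(colSums(pt$M), unname(pt$n))
  expect_true(all(pt$q >= 0 & pt$q <= 1))
  expect_error(presence_table(corp, g, region_presets()$Up, k = 0),
               "k must be")
})

test_that("stratified presence frequencies are tallied per row", {
  # 4 exons in 2 rows; motif present in both exons of row 1 only:
  # exons 1-2 get AT-rich Up windows carrying ACGTA, exons 3-4 all-C
  corp <- toy_corpus(4)
  L <- nchar(corp$up_flank[1])
  at_win <- paste(c(rep("A", 20), "ACGTA", rep("T", 25)), collapse = "")
  for (e in 1:2)
    substr(corp$up_flank[e], L - 64 + 1, L - 15 + 1) <- at_win
  for (e in 3:4)
    substr(corp$up_flank[e], L - 64 + 1, L - 15 + 1) <-
      paste(rep("C", 50), collapse = "")
  g <- gc_grid(corp, region_pairing("UpDp"), n_bins = 2)
  pt <- presence_table(corp, g, region_presets()$Up, k = 5)
  i <- match("ACGTA", all_kmers(5))
  expect_equal(unique(g$row[1:2]), 1L)   # low-GC row
  expect_equal(pt$q[1, i], 1)
  expect_equal(pt$q[2, i], 0)
})

test_that("corrected expectation follows the grid summation", {
  grid <- structure(list(n_bins = 2L, N = 40,
                         K = matrix(c(10, 10, 10, 10), 2, 2)),
                    class = "gc_grid")
  # hand summation: 10(.5*.2) + 10(.5*.3) + 10(.1*.2) + 10(.1*.3) = 3
  expect_equal(expected_pair_count(grid, c(0.5, 0.1), c(0.2, 0.3)), 3)
  expect_equal(expected_pair_count(grid, c(0, 0), c(0.2, 0.3)), 0)
  # uniform frequencies reduce to the unstratified mean nU*nD/N
  nU <- 8; nD <- 15
  expect_equal(expected_pair_count(grid, rep(nU / 40, 2), rep(nD / 40, 2)),
               nU * nD / 40)
  # matrix form agrees with elementwise form
  qU <- matrix(c(0.5, 0.1, 0.2, 0.6), 2)
  qD <- matrix(c(0.2, 0.3, 0.9, 0.4), 2)
  M <- expected_pair_count(grid, qU, qD)
  expect_equal(M[1, 1], expected_pair_count(grid, qU[, 1], qD[, 1]))
  expect_equal(M[2, 1], expected_pair_count(grid, qU[, 2], qD[, 1]))
})

test_that("margin adjustment rounds and clamps", {
  expect_equal(adjust_margin(100, 10, 2.04), 20)  # round(20.4)
  expect_equal(adjust_margin(100, 10, 0), 0)
  expect_equal(adjust_margin(100, 10, 1e6), 100)  # clamped to N
  expect_true(is.na(adjust_margin(100, 0, 5)))
  # the single-box case restores the unadjusted margin exactly
  N <- 57; nU <- 13; nD <- 22
  expect_equal(adjust_margin(N, nU, nU * nD / N), nD)
})

test_that("tail probabilities match explicit pmf summation", {
  # hand case: P(K >= 4 | N=20, nU=5, nD=4) = C(4,4) C(16,1) / C(20,5)
  pv <- pair_pvalue(20, 5, 4, 4)
  expect_equal(pv$p_upper, 16 / 15504)
  expect_equal(pv$direction, "enriched")
  # full sweep against the choose() oracle
  for (ka in 0:4) {
    pv <- pair_pvalue(20, 5, 4, ka)
    o <- oracle_tails(ka, 20, 5, 4)
    expect_equal(pv$p_upper, o$p_upper, tolerance = 1e-12)
    expect_equal(pv$p_lower, o$p_lower, tolerance = 1e-12)
  }
  # degenerate margins
  pv0 <- pair_pvalue(20, 5, 4, 0)
  expect_equal(pv0$p_upper, 1)
  pv_full <- pair_pvalue(20, 20, 7, 7)  # motif in every upstream region
  expect_equal(pv_full$p_upper, 1)
  expect_error(pair_pvalue(20, 5, 25, 2), "invalid")
  # out-of-support observation is flagged, tail = support point mass
  pv_o <- pair_pvalue(20, 5, 2, 4)
  expect_true(pv_o$flagged)
  expect_equal(pv_o$p_upper, oracle_hyper_pmf(2, 20, 5, 2))
})

test_that("single-box scan equals the plain hypergeometric test", {
  corp <- toy_corpus(80, seed = 11)
  fit <- bbcooc(corp, k = 2, n_bins = 1)
  m <- 4^2
  up <- extract_region(corp, region_presets()$Up)
  dn <- extract_region(corp, region_presets()$Dp)
  for (u in seq_len(m)) for (d in seq_len(m)) {
    nU <- fit$n_U[u]; nD <- fit$n_D[d]; ka <- fit$k_a[u, d]
    expect_identical(fit$n_adj[u, d], as.double(nD))
    if (nU == 0) next
    expect_equal(fit$p_upper[u, d],
                 stats::phyper(ka - 1, nD, 80 - nD, nU,
                               lower.tail = FALSE), tolerance = 1e-14)
  }
  # margins computed independently by string matching
  expect_equal(unname(fit$n_U[match("AC", all_kmers(2))]),
               sum(grepl("AC", up, fixed = TRUE)))
})

test_that("vectorized scan equals the naive loop oracle", {
  corp <- toy_corpus(60, seed = 13)
  pairing <- region_pairing("UpDp")
  fit <- bbcooc(corp, pairing, k = 2, n_bins = 4)
  o <- oracle_scan(corp, pairing, k = 2, n_bins = 4)
  idx <- cbind(o$u, o$d)
  expect_identical(as.integer(fit$k_a[idx]), as.integer(o$k_a))
  expect_equal(fit$k_prime[idx], o$k_prime, tolerance = 1e-12)
  ok <- !is.na(o$n_adj)
  expect_equal(fit$n_adj[idx][ok], o$n_adj[ok])
  expect_equal(fit$p_upper[idx], o$p_upper, tolerance = 1e-12)
  expect_equal(fit$p_lower[idx], o$p_lower, tolerance = 1e-12)
})

test_that("alternative margin-adjustment sides give similar results", {
  sim <- simulate_corpus(n_exons = 500, seed = 17, planted = list(
    plant_pair("ACG", "TGC", f_both = 0.35)))
  fit_d <- bbcooc(sim$corpus, k = 3, n_bins = 5)
  fit_u <- bbcooc(sim$corpus, k = 3, n_bins = 5, adjust = "up")
  fit_b <- bbcooc(sim$corpus, k = 3, n_bins = 5, adjust = "both")
  key <- function(f) paste(f$significant$motif_u, f$significant$motif_d)
  expect_true(paste("ACG", "TGC") %in% key(fit_d))
  expect_true(paste("ACG", "TGC") %in% key(fit_u))
  expect_true(paste("ACG", "TGC") %in% key(fit_b))
})

test_that("scan object reports the full hypothesis space", {
  corp <- toy_corpus(50, seed = 19)
  fit <- bbcooc(corp, k = 2, n_bins = 2)
  expect_equal(summary(fit)$n_hypotheses, 4^4)
  expect_equal(dim(fit$p_upper), c(16, 16))
  df <- as.data.frame(fit, all = TRUE)
  expect_equal(nrow(df), 4^4)
  expect_true(all(df$k_a <= pmin(df$n_Ui, df$n_Dj)))
  expect_error(bbcooc(corp[0, ], k = 2), "empty")
})

test_that("cross-region evaluation is consistent and flags power", {
  sim <- simulate_corpus(n_exons = 800, seed = 23, planted = list(
    plant_pair("ACG", "TGC", pairing = "UpDp", f_both = 0.4)))
  fit <- bbcooc(sim$corpus, k = 3, n_bins = 5)
  expect_true(nrow(fit$significant) >= 1)
  # self-evaluation returns the defining scan's p-values
  self <- cross_region_pvalues(fit, sim$corpus, list("UpDp"))
  iu <- match(fit$significant$motif_u, fit$motifs)
  id <- match(fit$significant$motif_d, fit$motifs)
  expect_equal(self$p_upper, fit$p_upper[cbind(iu, id)])
  expect_true(all(self$expected_within_2x))
  # a pair planted only in UpDp is not significant in UdDd
  other <- cross_region_pvalues(fit, sim$corpus, list("UdDd"))
  planted_row <- other$motif_u == "ACG" & other$motif_d == "TGC"
  expect_true(all(other$p_upper[planted_row] > fit$alpha))
})
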