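test_that("motif coverage is the union of occupied intervals", {
  expect_equal(motif_coverage("ACGTACGTACGT",
                              hexamer_set(c("ACGTAC", "GTACGT"))), 1)
  expect_equal(motif_coverage("AAAAAAAAAA", hexamer_set("CCCCCC")), 0)
  # hand interval union: hits at 0-based 1 and 4 cover 1..9 of 12
  s <- "TACGTACCCGTT"
  hexes <- hexamer_set(c(substr(s, 2, 7), substr(s, 5, 10)))
  expect_equal(motif_coverage(s, hexes), 9 / 12)
  expect_warning(cov <- motif_coverage("ACG", hexamer_set("ACGTAC")),
                 "shorter")
  expect_equal(cov, 0)
  expect_error(hexamer_set("ACGT"), "6-mers")
})

test_that("motif coverage is monotone in the hexamer set", {
  set.seed(41)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
          collapse = ""), character(1))
  small <- hexamer_set(c("ACGTAC", "GGGAAA"))
  big <- hexamer_set(c("ACGTAC", "GGGAAA", "TTTTGG", "CACACA"))
  expect_true(all(motif_coverage(seqs, big) >=
                    motif_coverage(seqs, small)))
})

test_that("GC-matched partition equalizes window GC histograms", {
  sim <- simulate_corpus(n_exons = 600, seed = 43, planted = list(
    plant_pair("ACG", "TGC", f_both = 0.3)))
  fit <- bbcooc(sim$corpus, k = 3, n_bins = 5)
  part <- gc_matched_partition(sim$corpus, fit, seed = 2)
  expect_gt(length(part$with_pairs), 0)
  expect_equal(length(part$with_pairs), length(part$without_pairs))
  expect_length(intersect(part$with_pairs, part$without_pairs), 0)
  p <- fit$pairing
  for (spec in list(p$upstream, p$downstream)) {
    a <- sim$corpus[match(part$with_pairs, sim$corpus$exon_id), ]
    b <- sim$corpus[match(part$without_pairs, sim$corpus$exon_id), ]
    gc_a <- sort(gc_content(extract_region(a, spec)))
    gc_b <- sort(gc_content(extract_region(b, spec)))
    expect_equal(gc_a, gc_b)
  }
  # with no significant pairs both sets are empty
  fit0 <- bbcooc(toy_corpus(60), k = 2, n_bins = 2)
  fit0$significant <- fit0$significant[0, ]
  part0 <- gc_matched_partition(toy_corpus(60), fit0)
  expect_length(part0$with_pairs, 0)
  expect_length(part0$without_pairs, 0)
})

test_that("strength comparison behaves at the null and under a shift", {
  sim <- simulate_corpus(n_exons = 200, seed = 45)
  corp <- sim$corpus
  ese <- hexamer_set(c("GAAGAA", "GGAAGG"), "ESE")
  ess <- hexamer_set(c("TTTGGG", "TAGGGT"), "ESS")
  pwms <- list(acceptor = estimate_pwm(corp, "acceptor"),
               donor = estimate_pwm(corp, "donor"))
  ids <- corp$exon_id[1:100]
  same <- compare_exon_strength(corp, ids, ids, ese, ess, pwms)
  expect_equal(same$mean_A, same$mean_B)
  expect_true(all(same$p_value == 1))
  # disjoint draws from one distribution: no significant difference
  # expected at these sizes; mostly checks plumbing and shapes
  cmp <- compare_exon_strength(corp, corp$exon_id[1:100],
                               corp$exon_id[101:200], ese, ess, pwms,
                               test = "wilcoxon")
  expect_setequal(cmp$feature, c("ese_coverage", "ess_coverage",
                                 "acceptor_cv", "donor_cv"))
  expect_true(all(cmp$n_A == 100 & cmp$n_B == 100))
  expect_error(compare_exon_strength(corp, character(), ids, ese),
               "non-empty")
})

test_that("a planted acceptor-strength difference is detected", {
  # weaken acceptors of the first group by scrambling the
  # polypyrimidine tract
  sim <- simulate_corpus(n_exons = 400, seed = 47)
  corp <- sim$corpus
  weak <- corp$exon_id[1:200]
  rows <- match(weak, corp$exon_id)
  set.seed(1)
  for (r in rows) {
    w <- corp$acceptor_window[r]
    substr(w, 1, 10) <- paste(sample(c("A", "G"), 10, replace = TRUE),
                              collapse = "")
    corp$acceptor_window[r] <- w
  }
  # score against a consensus estimated from the authentic sites
  ref <- corp[201:400, ]
  pwms <- list(acceptor = estimate_pwm(ref, "acceptor"),
               donor = estimate_pwm(ref, "donor"))
  cmp <- compare_exon_strength(corp, weak, corp$exon_id[201:400],
                               pwms = pwms)
  acc <- cmp[cmp$feature == "acceptor_cv", ]
  expect_lt(acc$mean_A, acc$mean_B)
  expect_lt(acc$p_value, 0.05)
})

test_that("display normalization centers and rescales to [-1, 1]", {
  expect_equal(normalize_for_display(10, 10), list(a = 0, b = 0))
  expect_equal(normalize_for_display(8, 12), list(a = -1, b = 1))
  set.seed(49)
  a <- rnorm(10); b <- rnorm(10)
  out <- normalize_for_display(a, b)
  expect_true(all(abs(c(out$a, out$b)) <= 1))
  expect_equal(max(abs(c(out$a, out$b))), 1)
  expect_equal(out$a + out$b, rep(0, 10))  # centered on pair midpoints
})
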