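test_that("identical orthologs give conservation exactly 1", {
  sim <- simulate_corpus(n_exons = 300, seed = 51, planted = list(
    plant_pair("ACG", "TGC", f_both = 0.4)))
  orth <- generate_orthologs(sim$corpus, sim$truth, mu = 0,
                             rho_pair = 1, rho_single = 1, seed = 1)
  expect_identical(orth$up_flank, sim$corpus$up_flank)
  pairs <- data.frame(motif_u = "ACG", motif_d = "TGC")
  res <- pairing_conservation(sim$corpus, orth, pairs,
                              region_pairing("UpDp"))
  expect_equal(res$proportion, c(1, 1))
  expect_false(any(res$flagged))
})

test_that("scrambled orthologs give the background presence rate", {
  sim <- simulate_corpus(n_exons = 2000, seed = 53, gc_corr = 0.5,
                         planted = list(plant_pair("ACG", "TGC",
                                                   f_both = 0.5)))
  # fully mutated flanks: conservation of the partner reduces to the
  # chance that a 3-mer occurs anywhere in a random 50-nt window
  orth <- generate_orthologs(sim$corpus, sim$truth, mu = 1,
                             rho_pair = 0, rho_single = 0, seed = 2)
  expect_true(all(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]) == 0,
    sim$corpus$up_flank[1:5], orth$up_flank[1:5])))
  pairs <- data.frame(motif_u = "ACG", motif_d = "TGC")
  res <- pairing_conservation(sim$corpus, orth, pairs,
                              region_pairing("UpDp"))
  # closed form (iid approximation): 1 - (1 - 4^-3)^48
  p_bg <- 1 - (1 - 4^-3)^48
  expect_true(all(abs(res$proportion - p_bg) < 0.08))
})

test_that("paired retention above single retention is recovered", {
  ok <- sapply(1:5, function(s) {
    # TAGTC is planted alone downstream so the non-co-occurring
    # control pair (ACGTA, TAGTC) has enough carriers to condition on
    sim <- simulate_corpus(n_exons = 3000, seed = s, planted = list(
      plant_pair("ACGTA", "TTGCA", f_both = 0.25, f_u = 0.15,
                 f_d = 0.15),
      plant_pair("ACGTA", "TAGTC", f_both = 0, f_d = 0.3)))
    orth <- generate_orthologs(sim$corpus, sim$truth, mu = 0.25,
                               rho_pair = 0.9, rho_single = 0.4,
                               seed = s)
    pairs <- data.frame(motif_u = "ACGTA", motif_d = "TTGCA")
    ctrl <- data.frame(motif_u = "ACGTA", motif_d = "TAGTC")
    res <- pairing_conservation(sim$corpus, orth, pairs,
                                region_pairing("UpDp"),
                                control_pairs = ctrl)
    co <- res$proportion[res$group == "co_occurring"]
    ct <- res$proportion[res$group == "control"]
    all(co > ct)
  })
  expect_true(all(ok))
})

test_that("motif retention frequency matches rho", {
  sim <- simulate_corpus(n_exons = 2000, seed = 55, planted = list(
    plant_pair("ACGTA", "TTGCA", f_both = 0.3)))
  orth <- generate_orthologs(sim$corpus, sim$truth, mu = 0.5,
                             rho_pair = 0.7, rho_single = 0.7, seed = 3)
  tr <- sim$truth[sim$truth$side == "up", ]
  kept <- mapply(function(id, pos, m) {
    substr(orth$up_flank[match(id, orth$exon_id)], pos,
           pos + nchar(m) - 1) == m
  }, tr$exon_id, tr$flank_pos, tr$motif)
  # retained intact w.p. rho, plus a sliver of chance survival
  expect_true(abs(mean(kept) - 0.7) < 0.05)
})

test_that("control motifs keep composition, lose association", {
  sim <- simulate_corpus(n_exons = 800, seed = 57, planted = list(
    plant_pair("ACG", "TGC", f_both = 0.4)))
  fit <- bbcooc(sim$corpus, k = 3, n_bins = 5)
  pairs <- data.frame(motif_u = "ACG", motif_d = "TGC")
  ctrl <- select_control_motifs(fit, pairs, side = "down", seed = 5)
  expect_equal(nrow(ctrl), 1)
  gc_of <- function(m) nchar(gsub("[^GC]", "", m))
  expect_equal(gc_of(ctrl$motif_d), gc_of("TGC"))
  iu <- match("ACG", fit$motifs); id <- match(ctrl$motif_d, fit$motifs)
  expect_gt(fit$p_upper[iu, id], 0.05)
  # deterministic under the same seed
  ctrl2 <- select_control_motifs(fit, pairs, side = "down", seed = 5)
  expect_identical(ctrl, ctrl2)
  # impossible pool: every same-GC candidate "significant"
  fit2 <- fit
  fit2$p_upper[,] <- 0
  ctrl3 <- select_control_motifs(fit2, pairs, side = "down", seed = 5)
  expect_equal(nrow(ctrl3), 0)
  expect_equal(nrow(attr(ctrl3, "dropped")), 1)
})

test_that("SNP density distinguishes paired from lone occurrences", {
  sim <- simulate_corpus(n_exons = 1500, seed = 59, planted = list(
    plant_pair("ACGTA", "TTGCA", f_both = 0.25, f_u = 0.2, f_d = 0.2)))
  pairs <- data.frame(motif_u = "ACGTA", motif_d = "TTGCA")
  # empty SNP table: both proportions zero
  empty <- data.frame(exon_id = character(), side = character(),
                      pos = integer())
  r0 <- snp_motif_density(sim$corpus, empty, pairs,
                          region_pairing("UpDp"))
  expect_equal(r0$paired$proportion, 0)
  expect_equal(r0$alone$proportion, 0)
  # uniform SNP rate r: both proportions near 1 - (1 - r)^k
  snps <- generate_snps(sim$corpus, sim$truth, base_rate = 0.02,
                        paired_multiplier = 1, seed = 4)
  r1 <- snp_motif_density(sim$corpus, snps, pairs,
                          region_pairing("UpDp"))
  expected <- 1 - (1 - 0.02)^5
  expect_true(abs(r1$paired$proportion - expected) < 0.03)
  expect_true(abs(r1$alone$proportion - expected) < 0.03)
  # halved rate inside paired motifs: paired < alone, significant
  snps2 <- generate_snps(sim$corpus, sim$truth, base_rate = 0.04,
                         paired_multiplier = 0.5, seed = 5)
  r2 <- snp_motif_density(sim$corpus, snps2, pairs,
                          region_pairing("UpDp"))
  expect_lt(r2$paired$proportion, r2$alone$proportion)
  expect_lt(r2$p_value, 0.05)
  # duplicating every exon leaves the proportions unchanged
  dup <- sim$corpus
  dup$exon_id <- paste0(dup$exon_id, "_b")
  both <- exon_corpus(rbind(as.data.frame(unclass(sim$corpus)),
                            as.data.frame(unclass(dup))))
  snps_dup <- rbind(snps2,
                    transform(snps2, exon_id = paste0(exon_id, "_b")))
  r3 <- snp_motif_density(both, snps_dup, pairs, region_pairing("UpDp"))
  expect_equal(r3$paired$proportion, r2$paired$proportion)
  expect_equal(r3$alone$proportion, r2$alone$proportion)
})
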