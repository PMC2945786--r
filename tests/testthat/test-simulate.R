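test_that("the generator is byte-deterministic given a seed", {
  a <- simulate_corpus(n_exons = 80, seed = 71, planted = list(
    plant_pair("ACGTA", "TTGCA", f_both = 0.2, f_u = 0.05, f_d = 0.05)))
  b <- simulate_corpus(n_exons = 80, seed = 71, planted = list(
    plant_pair("ACGTA", "TTGCA", f_both = 0.2, f_u = 0.05, f_d = 0.05)))
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth, b$truth)
  c <- simulate_corpus(n_exons = 80, seed = 72)
  expect_false(identical(a$corpus$up_flank, c$corpus$up_flank))
})

test_that("records are structurally coherent", {
  sim <- simulate_corpus(n_exons = 50, seed = 73)
  corp <- sim$corpus
  expect_s3_class(corp, "exon_corpus")
  expect_true(all(nchar(corp$up_flank) == 100))
  expect_true(all(nchar(corp$down_flank) == 100))
  # welded splice-site windows: acceptor = last 14 intron nt + first
  # exon base; donor = last 3 exon nt + first 6 intron nt
  expect_identical(paste0(substr(corp$up_flank, 87, 100),
                          substr(corp$exon_seq, 1, 1)),
                   corp$acceptor_window)
  L <- nchar(corp$exon_seq[1])
  expect_identical(paste0(substr(corp$exon_seq, L - 2, L),
                          substr(corp$down_flank, 1, 6)),
                   corp$donor_window)
  # canonical dinucleotides always present
  expect_true(all(substr(corp$up_flank, 99, 100) == "AG"))
  expect_true(all(substr(corp$down_flank, 1, 2) == "GT"))
})

test_that("truth ledger matches the emitted sequences exactly", {
  sim <- simulate_corpus(n_exons = 400, seed = 75, planted = list(
    plant_pair("ACGTA", "TTGCA", f_both = 0.3, f_u = 0.1, f_d = 0.1),
    plant_pair("GGGCG", "CCCTA", f_both = 0.15)))
  tr <- sim$truth
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    e <- match(tr$exon_id[i], sim$corpus$exon_id)
    fl <- if (tr$side[i] == "up") sim$corpus$up_flank[e] else
      sim$corpus$down_flank[e]
    expect_identical(substr(fl, tr$flank_pos[i],
                            tr$flank_pos[i] + nchar(tr$motif[i]) - 1L),
                     tr$motif[i])
  }
  # planted_as marks joint vs single planting
  expect_setequal(unique(tr$planted_as), c("pair", "single"))
  # planted fractions are honored (binomial tolerance)
  n_pair_u <- length(unique(tr$exon_id[tr$planted_as == "pair" &
                                         tr$motif == "ACGTA"]))
  expect_true(abs(n_pair_u / 400 - 0.3) < 0.08)
})

test_that("flank-GC correlation hits the calibrated target", {
  sim <- simulate_corpus(n_exons = 20000, seed = 77)
  up <- extract_region(sim$corpus, region_presets()$Up)
  dn <- extract_region(sim$corpus, region_presets()$Dp)
  r <- cor(gc_content(up), gc_content(dn))
  expect_true(abs(r - 0.73) < 0.05)
  # calibration is monotone in the isochore/noise variance ratio
  sds <- vapply(c(0.3, 0.5, 0.7, 0.9), calibrate_isochore_sd,
                numeric(1), flank_noise_sd = 0.03)
  expect_true(all(diff(sds) > 0))
})

test_that("motif longer than its window is refused", {
  long <- paste(rep("A", 60), collapse = "")
  expect_error(simulate_corpus(n_exons = 20, seed = 79, planted = list(
    plant_pair(long, "TTGCA", f_both = 0.2))), "longer than")
})

test_that("ortholog generation honors boundary rates", {
  sim <- simulate_corpus(n_exons = 60, seed = 81, planted = list(
    plant_pair("ACGTA", "TTGCA", f_both = 0.3)))
  same <- generate_orthologs(sim$corpus, sim$truth, mu = 0,
                             rho_pair = 1, rho_single = 1, seed = 1)
  expect_identical(same$up_flank, sim$corpus$up_flank)
  expect_identical(same$down_flank, sim$corpus$down_flank)
  allmut <- generate_orthologs(sim$corpus, sim$truth, mu = 1,
                               rho_pair = 1, rho_single = 1, seed = 1)
  # every base substituted except protected motifs
  tr1 <- sim$truth[1, ]
  e <- match(tr1$exon_id, sim$corpus$exon_id)
  fl <- if (tr1$side == "up") allmut$up_flank[e] else allmut$down_flank[e]
  expect_identical(substr(fl, tr1$flank_pos, tr1$flank_pos + 4), tr1$motif)
  # outside motifs, nothing survives
  a <- strsplit(sim$corpus$up_flank[1], "")[[1]]
  b <- strsplit(allmut$up_flank[1], "")[[1]]
  prot <- unlist(lapply(which(sim$truth$exon_id ==
                                sim$corpus$exon_id[1] &
                                sim$truth$side == "up"), function(i)
    sim$truth$flank_pos[i]:(sim$truth$flank_pos[i] + 4)))
  free <- setdiff(seq_along(a), prot)
  expect_true(all(a[free] != b[free]))
})

test_that("SNP tables track the configured rates", {
  sim <- simulate_corpus(n_exons = 1000, seed = 83)
  expect_equal(nrow(generate_snps(sim$corpus, sim$truth, 0, 1,
                                  seed = 1)), 0)
  snps <- generate_snps(sim$corpus, sim$truth, 0.01, 1, seed = 1)
  dens <- nrow(snps) / (1000 * 200)
  expect_true(abs(dens - 0.01) < 0.002)
  expect_true(all(snps$pos >= 1 & snps$pos <= 100))
})
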