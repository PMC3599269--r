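test_that("apply_variants respects support, order and reference checks", {
  genome <- c(c1 = "AACCGGTTAACC")
  # sub-threshold support is rejected
  low <- make_variants("c1", 5, "G", "T", 0.59)
  r <- apply_variants(genome, low)
  expect_equal(nrow(r$applied), 0L)
  expect_equal(r$rejected$reason, "support")
  expect_identical(r$genome, genome)

  # right-to-left application: a deletion at pos 5 does not shift a SNP
  # at pos 2 applied in the same batch
  batch <- make_variants("c1", c(5, 2), c("G", "C"), c("", "T"),
                         c(0.9, 0.9))
  r2 <- apply_variants(genome, batch)
  expect_equal(nrow(r2$applied), 2L)
  expect_equal(unname(r2$genome["c1"]), "AATCGTTAACC")

  # ref mismatch is rejected and logged, never applied
  bad <- make_variants("c1", 0, "G", "T", 0.9)
  r3 <- apply_variants(genome, bad)
  expect_equal(r3$rejected$reason, "ref_mismatch")
  expect_identical(r3$genome, genome)

  # overlapping accepted calls: higher support wins
  ov <- make_variants("c1", c(3, 3), c("C", "C"), c("A", "G"),
                      c(0.7, 0.95))
  r4 <- apply_variants(genome, ov)
  expect_equal(nrow(r4$applied), 1L)
  expect_equal(r4$applied$alt, "G")
  expect_equal(r4$rejected$reason, "overlap")

  # length accounting
  ins <- make_variants("c1", c(2, 6), c("", "T"), c("GGG", ""),
                       c(0.8, 0.8))
  r5 <- apply_variants(genome, ins)
  expect_equal(nchar(r5$genome), nchar(genome) + 3 - 1,
               ignore_attr = TRUE)
})

test_that("restoring planted errors returns the genome to truth", {
  run <- simulate_ancestor(1, 30, 150, rng_seed = 19)
  pe <- plant_assembly_errors(run$genome, n_snp = 25, n_indel = 40,
                              rng_seed = 20)
  expect_false(identical(pe$genome, run$genome))
  calls <- restoring_calls(pe$edits)
  r <- apply_variants(pe$genome, calls)
  expect_identical(unname(r$genome[names(run$genome)]),
                   unname(run$genome))
})

test_that("polishing reaches a fixed point and detects the trivial one", {
  run <- simulate_ancestor(1, 20, 150, rng_seed = 23)
  pe <- plant_assembly_errors(run$genome, n_snp = 10, n_indel = 15,
                              rng_seed = 24)
  caller <- make_truth_caller(run$genome, pe$edits)

  # already-true genome: one round, zero applied
  r0 <- polish_iterate(run$genome, caller)
  expect_equal(nrow(r0$rounds), 1L)
  expect_equal(r0$rounds$n_snps_applied + r0$rounds$n_indels_applied, 0L)

  r <- polish_iterate(pe$genome, caller)
  expect_identical(unname(r$genome[names(run$genome)]),
                   unname(run$genome))
  expect_lte(nrow(r$rounds), 2L)
  final <- r$rounds[nrow(r$rounds), ]
  expect_equal(final$n_snps_applied + final$n_indels_applied, 0L)
})

test_that("noisy-support polishing applies a non-increasing call stream", {
  ok <- vapply(1:20, function(s) {
    run <- simulate_ancestor(1, 15, 150, rng_seed = 100 + s)
    pe <- plant_assembly_errors(run$genome, n_snp = 10, n_indel = 10,
                                rng_seed = 200 + s)
    set.seed(300 + s)
    support <- rbeta(20, 8, 2)   # some calls fall below 0.6
    caller <- make_truth_caller(run$genome, pe$edits, support = support)
    r <- polish_iterate(pe$genome, caller)
    applied <- r$rounds$n_snps_applied + r$rounds$n_indels_applied
    all(diff(applied) <= 0)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("N50 and related metrics match definitions", {
  m <- assembly_metrics(c(2, 2, 2, 3, 3, 4, 8, 8), min_len = 0)
  expect_equal(m$n50, 8)
  expect_equal(m$total_len, 32)
  expect_equal(assembly_metrics(1234, min_len = 0)$n50, 1234)
  m2 <- assembly_metrics(c(500, 499), min_len = 500)
  expect_equal(m2$n_contigs, 1L)
  expect_equal(m2$total_len, 500)
})

test_that("gap statistics match the run-length definition", {
  g <- gap_stats("ACGTNNNACGTNA")
  expect_equal(g$n_gaps, 2L)
  expect_equal(g$min_gap, 1)
  expect_equal(g$max_gap, 3)
  expect_equal(g$mean_gap, 2)
  g0 <- gap_stats("ACGTACGT")
  expect_equal(g0, list(n_gaps = 0L, mean_gap = 0, min_gap = 0,
                        max_gap = 0))
})

test_that("coverage windows normalise to the genome mean with tail merging", {
  depth <- list(c1 = rep(50, 2400))
  cw <- coverage_windows(depth, window = 1000)
  expect_true(all(cw$log2_ratio == 0))
  # 400-bp tail (under half a window) merged into the previous window
  expect_equal(nrow(cw), 2L)
  expect_equal(cw$win_end[2], 2400)

  depth2 <- list(c1 = c(rep(50, 1000), rep(100, 1000)))
  cw2 <- coverage_windows(depth2, window = 1000)
  expect_equal(cw2$log2_ratio[2] - cw2$log2_ratio[1], 1, tolerance = 1e-12)

  # planted 3-copy region recovered within 0.2 of log2(3)
  run <- simulate_ancestor(1, 30, 150, rng_seed = 31)
  cn <- data.frame(chrom = names(run$genome)[1], start = 3000, end = 6000,
                   copy = 3)
  sim <- simulate_depth_and_variants(run$genome, run$genome,
                                     mean_depth = 60, rng_seed = 32,
                                     cn_regions = cn)
  cw3 <- coverage_windows(sim$depth, window = 1000)
  inside <- cw3$win_start >= 3000 & cw3$win_end <= 6000
  expect_true(any(inside))
  # the 3x region inflates the genome-wide mean, so compare against the
  # baseline windows
  baseline <- median(cw3$log2_ratio[!inside])
  expect_true(all(abs(cw3$log2_ratio[inside] - baseline - log2(3)) < 0.2))
})
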