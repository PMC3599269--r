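test_that("ancestor simulation builds well-formed, seed-deterministic genomes", {
  run <- simulate_ancestor(1, 3, 100, rng_seed = 7)
  expect_length(run$genome, 1L)
  expect_equal(nrow(run$genes), 3L)
  for (i in seq_len(nrow(run$genes))) {
    cds <- cds_sequence(run$genes[i, ], run$genome)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }

  a <- simulate_ancestor(2, 10, 120, rng_seed = 42)
  b <- simulate_ancestor(2, 10, 120, rng_seed = 42)
  c <- simulate_ancestor(2, 10, 120, rng_seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$genome, c$genome))

  expect_equal(nrow(simulate_ancestor(3, 5, 100, rng_seed = 1)$genes), 15L)
  expect_error(simulate_ancestor(1, 2, 100), "genes_per_chrom")
})

test_that("evolve with all-zero parameters is the identity", {
  run <- simulate_ancestor(2, 10, 120, rng_seed = 3)
  p0 <- evolution_params(sub_rate = 0, hp_indel_rate = 0,
                         gene_loss_prob = 0, rng_seed = 1)
  d <- evolve(run$genome, run[c("genes", "trnas")], p0)
  expect_identical(unname(d$genome), unname(run$genome))
  expect_equal(length(d$truth$pairs), nrow(run$genes))
  expect_equal(length(d$truth$lost), 0L)
  expect_equal(unname(d$genes$start), unname(run$genes$start))
})

test_that("evolve conserves the gene ledger and plants indels inside runs", {
  run <- simulate_ancestor(2, 40, 150, rng_seed = 9)
  par <- evolution_params(sub_rate = 0.03, hp_indel_rate = 0.03,
                          gene_loss_prob = 0.05, n_inversions = 1,
                          n_translocations = 1, rng_seed = 11)
  d <- evolve(run$genome, run[c("genes", "trnas")], par)
  expect_equal(length(d$truth$pairs) + length(d$truth$lost),
               nrow(run$genes))
  expect_false(any(names(d$truth$pairs) %in% d$truth$lost))
  # 1-to-1: no duplicated targets
  expect_false(anyDuplicated(d$truth$pairs) > 0)

  hp <- d$truth$hp_indels
  expect_gt(nrow(hp), 0)
  for (i in seq_len(nrow(hp))) {
    s <- d$genome[[hp$chrom[i]]]
    # the recorded position carries the run's base in the derived genome
    expect_equal(substr(s, hp$pos[i] + 1, hp$pos[i] + 1), hp$base[i])
    expect_gte(hp$run_len[i], par$min_run)
  }
})

test_that("a translocation breaks exactly two gene adjacencies", {
  run <- simulate_ancestor(2, 30, 150, rng_seed = 5)
  par <- evolution_params(sub_rate = 0, hp_indel_rate = 0,
                          gene_loss_prob = 0, n_translocations = 1,
                          rng_seed = 2)
  d <- evolve(run$genome, run[c("genes", "trnas")], par)
  # adjacency oracle: count ancestor-adjacent gene pairs whose partners
  # are no longer adjacent in the descendant
  anc_ord <- gene_order(run$genes)
  der_ord <- gene_order(d$genes)
  di <- setNames(der_ord$index$idx, der_ord$index$gene_id)
  dc <- setNames(der_ord$index$chrom, der_ord$index$gene_id)
  breaks <- 0L
  for (chrom in names(anc_ord$by_chrom)) {
    ids <- anc_ord$by_chrom[[chrom]]
    for (i in seq_len(length(ids) - 1L)) {
      p1 <- d$truth$pairs[ids[i]]; p2 <- d$truth$pairs[ids[i + 1L]]
      if (!(dc[p1] == dc[p2] && abs(di[p1] - di[p2]) == 1L))
        breaks <- breaks + 1L
    }
  }
  expect_equal(breaks, 2L)
})

test_that("hit tables expose the decoy failure mode with contiguous ranks", {
  run <- simulate_ancestor(1, 20, 120, rng_seed = 8)
  p0 <- evolution_params(sub_rate = 0.01, rng_seed = 4)
  d <- evolve(run$genome, run[c("genes", "trnas")], p0)

  clean <- make_hit_table(run$genes, d$genes, d$truth, decoy_prob = 0,
                          rng_seed = 1)
  hg <- map_top_hits_to_genes(clean, d$genes)
  top1 <- hg$gene_id[hg$rank == 1L]
  names(top1) <- hg$query_id[hg$rank == 1L]
  expect_true(all(top1[names(d$truth$pairs)] == d$truth$pairs))

  decoyed <- make_hit_table(run$genes, d$genes, d$truth, decoy_prob = 1,
                            rng_seed = 1)
  hg2 <- map_top_hits_to_genes(decoyed, d$genes)
  top2 <- setNames(hg2$gene_id[hg2$rank == 1L], hg2$query_id[hg2$rank == 1L])
  expect_true(all(top2[names(d$truth$pairs)] != d$truth$pairs))

  for (q in unique(decoyed$query_id)) {
    r <- sort(decoyed$rank[decoyed$query_id == q])
    expect_equal(r, seq_along(r))
  }
})

test_that("depth/variant simulation separates true and false calls by support", {
  run <- simulate_ancestor(1, 10, 120, rng_seed = 6)
  # identical genomes, no error: empty call set
  sim0 <- simulate_depth_and_variants(run$genome, run$genome,
                                      error_frac = 0, rng_seed = 1)
  expect_equal(nrow(sim0$calls), 0L)
  expect_equal(lengths(sim0$depth), nchar(run$genome),
               ignore_attr = TRUE)

  pe <- plant_assembly_errors(run$genome, n_snp = 15, n_indel = 20,
                              rng_seed = 2)
  rest <- restoring_calls(pe$edits)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  frac_ok <- vapply(1:20, function(s) {
    sim <- simulate_depth_and_variants(run$genome, pe$genome,
                                       edits = pe$edits,
                                       error_frac = 2e-4, rng_seed = s)
    is_true <- key(sim$calls) %in% key(rest)
    mean(sim$calls$support[is_true] >= 0.6)
  }, numeric(1))
  expect_gte(mean(frac_ok), 0.95)

  sim <- simulate_depth_and_variants(run$genome, pe$genome,
                                     edits = pe$edits, error_frac = 5e-4,
                                     rng_seed = 3)
  false_calls <- sim$calls[!(key(sim$calls) %in% key(rest)), ]
  expect_gt(nrow(false_calls), 0)
  expect_true(all(false_calls$support < 0.6))
})

test_that("growth-curve simulation honours its three-phase contract", {
  gc <- simulate_growth_curve(120, 90, 1.0, noise_sd = 0)
  expect_equal(gc$time_min, seq(0, 4320, by = 20))
  before_lag <- gc$od[gc$time_min <= 120]
  expect_true(all(abs(before_lag - before_lag[1]) < 1e-12))
  expect_equal(max(gc$od) - min(gc$od), 1.0, tolerance = 1e-9)

  a <- simulate_growth_curve(100, 60, 0.8, noise_sd = 0.01, rng_seed = 5)
  b <- simulate_growth_curve(100, 60, 0.8, noise_sd = 0.01, rng_seed = 5)
  expect_identical(a, b)
})
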