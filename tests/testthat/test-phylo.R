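test_that("the substitution model is a proper reversible rate matrix", {
  for (mod in list(substitution_model("nt"),
                   substitution_model("aa"),
                   substitution_model("nt", c(0.4, 0.3, 0.2, 0.1)))) {
    expect_equal(rowSums(mod$Q), rep(0, length(mod$states)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sum(mod$freqs), 1, tolerance = 1e-12)
    # detailed balance
    db <- mod$freqs * mod$Q
    expect_equal(db, t(db), tolerance = 1e-12)
    P <- transition_matrix(mod, 0.37)
    expect_equal(rowSums(P), rep(1, length(mod$states)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(P >= 0))
    expect_equal(transition_matrix(mod, 0), diag(length(mod$states)),
                 tolerance = 1e-9)
  }
})

test_that("single-site, zero-branch likelihood is the stationary log-frequency", {
  mod <- substitution_model("nt", c(0.4, 0.3, 0.2, 0.1))
  tr <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(log_likelihood(c(A = "A", B = "A"), tr, mod),
               log(0.4), tolerance = 1e-9)
  # conflicting residues on a zero-length tree stay finite
  expect_true(is.finite(log_likelihood(c(A = "A", B = "C"), tr, mod)))
})

test_that("pruning equals exhaustive ancestral-state summation on small trees", {
  mod <- substitution_model("nt", c(0.3, 0.3, 0.25, 0.15))
  trees <- c("((A:0.1,B:0.25):0.07,(C:0.18,D:0.3):0.12);",
             "(((A:0.1,B:0.2):0.05,C:0.15):0.04,(D:0.2,E:0.1):0.09);")
  set.seed(17)
  for (txt in trees) {
    tr <- ape::read.tree(text = txt)
    aln <- simulate_alignment(tr, mod, 4)
    expect_equal(log_likelihood(aln, tr, mod),
                 brute_force_loglik(aln, tr, mod), tolerance = 1e-10)
    # with a gap in one taxon
    aln2 <- aln
    substr(aln2[1], 2, 2) <- "-"
    expect_equal(log_likelihood(aln2, tr, mod),
                 brute_force_loglik(aln2, tr, mod), tolerance = 1e-10)
  }
  # amino-acid mode on a 3-taxon toy
  ma <- substitution_model("aa")
  tra <- ape::read.tree(text = "((A:0.2,B:0.1):0.05,C:0.3);")
  alna <- simulate_alignment(tra, ma, 3, rng_seed = 5)
  expect_equal(log_likelihood(alna, tra, ma),
               brute_force_loglik(alna, tra, ma), tolerance = 1e-10)
})

test_that("likelihood is invariant to site order and pattern compression", {
  mod <- substitution_model("nt")
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.1,D:0.15):0.1);")
  aln <- simulate_alignment(tr, mod, 200, rng_seed = 8)
  base <- log_likelihood(aln, tr, mod)
  set.seed(9)
  perm <- sample.int(200)
  shuffled <- vapply(aln, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), "")
  expect_equal(log_likelihood(shuffled, tr, mod), base, tolerance = 1e-9)
  # per-site expansion sums to the total
  ps <- log_likelihood(aln, tr, mod, per_site = TRUE)
  expect_equal(sum(ps$site_logl), base, tolerance = 1e-9)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  mod <- substitution_model("nt")
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.3):0.1);")
  aln <- simulate_alignment(tr, mod, 300, rng_seed = 2)
  pdat <- phangorn::phyDat(t(sapply(aln, function(s) strsplit(s, "")[[1]])),
                           type = "DNA")
  ref <- phangorn::pml(tr, pdat, model = "JC")$logLik
  expect_equal(log_likelihood(aln, tr, mod), ref, tolerance = 1e-6)
})

test_that("two-taxon ML distance matches the closed-form inverse formula", {
  mod <- substitution_model("nt")
  gen <- ape::read.tree(text = "(A:0.08,B:0.08);")
  aln <- simulate_alignment(gen, mod, 60000, rng_seed = 13)
  p <- mean(strsplit(aln[["A"]], "")[[1]] != strsplit(aln[["B"]], "")[[1]])
  d_closed <- -3 / 4 * log(1 - 4 / 3 * p)
  fit <- optimize_branch_lengths(aln, gen, mod, tol = 1e-9)
  expect_equal(sum(fit$lengths), d_closed, tolerance = 1e-4)
})

test_that("branch-length optimisation never decreases the likelihood", {
  mod <- substitution_model("nt")
  tr <- ape::read.tree(
    text = "(((A:0.1,B:0.2):0.05,C:0.15):0.04,(D:0.2,E:0.1):0.09);")
  aln <- simulate_alignment(tr, mod, 400, rng_seed = 21)
  start <- tr
  start$edge.length <- rep(0.3, nrow(tr$edge))
  before <- log_likelihood(aln, start, mod)
  fit <- optimize_branch_lengths(aln, start, mod)
  expect_gte(fit$logL, before)
  expect_equal(log_likelihood(aln, fit$tree, mod), fit$logL,
               tolerance = 1e-6)
})

test_that("branch lengths are recovered from long simulated alignments", {
  mod <- substitution_model("nt")
  tr <- candidate_placements()$topo2
  set.seed(33)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.2)
  aln <- simulate_alignment(tr, mod, 100000, rng_seed = 34)
  fit <- optimize_branch_lengths(aln, tr, mod, tol = 1e-8)
  # root edges are identifiable only through their sum
  root <- ape::Ntip(tr) + 1L
  is_root_edge <- tr$edge[, 1] == root
  expect_equal(fit$lengths[!is_root_edge], tr$edge.length[!is_root_edge],
               tolerance = 0.05)
  expect_equal(sum(fit$lengths[is_root_edge]),
               sum(tr$edge.length[is_root_edge]), tolerance = 0.05)
})

test_that("gene-set sampling is deterministic, eligible-only and uniform", {
  fams <- list(
    f1 = c(A = "AA", B = "CC", C = "GG"),
    f2 = c(A = "AA", B = "CC", C = "GG"),
    f3 = c(A = "AA", B = "CC"),           # missing C: ineligible
    f4 = c(A = "AA", B = "CC", C = "GG"))
  s1 <- sample_gene_sets(fams, 2, 5, required_species = c("A", "B", "C"),
                         rng_seed = 4)
  s2 <- sample_gene_sets(fams, 2, 5, required_species = c("A", "B", "C"),
                         rng_seed = 4)
  expect_identical(s1, s2)
  expect_false(any(vapply(s1, function(x) "f3" %in% x, logical(1))))

  freq <- table(unlist(sample_gene_sets(fams, 2, 3000,
                                        required_species = c("A", "B", "C"),
                                        rng_seed = 5)))
  expected <- 3000 * 2 / 3
  sigma <- sqrt(3000 * (2 / 3) * (1 / 3))
  expect_true(all(abs(freq - expected) < 3 * sigma))
})

test_that("concatenation preserves length, species and likelihood", {
  mod <- substitution_model("nt")
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.1);")
  fams <- simulate_families(tr, mod, 4, 50, rng_seed = 6)
  cc <- concatenate_alignments(fams)
  expect_equal(unname(nchar(cc)), rep(200L, 3))
  # order invariance of the likelihood
  cc2 <- concatenate_alignments(fams[c(3, 1, 4, 2)])
  expect_equal(log_likelihood(cc, tr, mod),
               log_likelihood(cc2, tr, mod), tolerance = 1e-9)
  expect_error(concatenate_alignments(c(fams, list(bad = c(A = "A")))),
               "species")
})

test_that("placement ties break to the lowest topology index", {
  mod <- substitution_model("nt")
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  fams <- simulate_families(tr, mod, 6, 40, rng_seed = 44)
  cands <- list(topo1 = tr, topo2 = tr)  # identical candidates: ties
  pr <- place_species(fams, cands, model = mod, sample_count = 2,
                      genes_per_sample = 3, n_bootstrap = 10, rng_seed = 7)
  expect_true(all(pr$per_sample$best_topo == "topo1"))
  expect_equal(sum(pr$support_counts), 2)
  expect_true(length(pr$ties) >= 1)
})

test_that("median branch lengths summarise per-family fits", {
  mod <- substitution_model("nt")
  tr <- candidate_placements()$topo2
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  fams <- simulate_families(tr, mod, 6, 400, rate_jitter_sd = 0.2,
                            rng_seed = 9)
  mb <- median_branch_lengths(fams, tr, mod)
  expect_equal(mb$n_families_used, 6L)
  expect_length(mb$median_lengths, nrow(tr$edge))
  # invariant to family order
  mb2 <- median_branch_lengths(fams[c(4, 2, 6, 1, 3, 5)], tr, mod)
  expect_equal(mb$median_lengths, mb2$median_lengths, tolerance = 1e-6)
})
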