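test_that("hits resolve to genes by maximal exonic overlap, order-independent", {
  tg <- make_genes(c("t1", "t2"), "c1", "+",
                   start = c(100, 210), end = c(200, 300))
  h <- rank_hits(data.frame(
    query_id = c("q1", "q2", "q3"), chrom = "c1",
    start = c(100, 150, 400), end = c(200, 220, 450),
    strand = "+", score = c(10, 10, 10)))
  res <- map_top_hits_to_genes(h, tg)
  expect_equal(res$gene_id[res$query_id == "q1"], "t1")
  expect_equal(res$gene_id[res$query_id == "q2"], "t1")  # 50 bp vs 10 bp
  expect_true(is.na(res$gene_id[res$query_id == "q3"]))

  sh <- h[c(3, 1, 2), ]
  res2 <- map_top_hits_to_genes(sh, tg)
  expect_equal(res2[order(res2$query_id), ], res[order(res$query_id), ],
               ignore_attr = TRUE)
})

test_that("first pass assigns middles only for monotone consecutive triplets", {
  # query g1,g2,g3 on one chromosome; six target permutations of
  # consecutive indices -- only the two monotone ones assign the middle
  qg <- make_genes(paste0("q", 1:3), "c1", "+",
                   start = c(0, 100, 200), end = c(90, 190, 290))
  tg <- make_genes(paste0("t", 1:3), "c1", "+",
                   start = c(0, 100, 200), end = c(90, 190, 290))
  qo <- gene_order(qg); to <- gene_order(tg)
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2))
  for (p in perms) {
    top <- setNames(paste0("t", p), paste0("q", 1:3))
    asn <- assign_first_pass(qo, top, to)
    assigned <- asn$class[asn$query_id == "q2"] == "syntenic_first_pass"
    monotone <- all(diff(p) == 1) || all(diff(p) == -1)
    expect_equal(assigned, monotone, info = paste(p, collapse = ","))
  }
})

test_that("conflicting first-pass claims void both claimants", {
  # two query triplets whose middles both map to the same target gene
  qg <- make_genes(paste0("q", 1:6), c(rep("c1", 3), rep("c2", 3)), "+",
                   start = rep(c(0, 100, 200), 2),
                   end = rep(c(90, 190, 290), 2))
  tg <- make_genes(paste0("t", 1:3), "c1", "+",
                   start = c(0, 100, 200), end = c(90, 190, 290))
  top <- setNames(c("t1", "t2", "t3", "t1", "t2", "t3"), paste0("q", 1:6))
  asn <- assign_first_pass(gene_order(qg), top, gene_order(tg))
  expect_true(all(asn$class[asn$query_id %in% c("q2", "q5")] ==
                    "unassigned"))
})

test_that("rescue recovers decoyed genes from ranked hits inside the window", {
  pair <- make_pair(21, n_chrom = 1, genes = 30, decoy = 0.4)
  asn <- run_ortholog_pipeline(pair$anc$genes, pair$der$genes, pair$hits)
  tp <- pair$der$truth$pairs
  syn <- asn[asn$class == "syntenic_rescued", ]
  expect_gt(nrow(syn), 0)
  expect_true(all(tp[syn$query_id] == syn$target_id))
  # a rescued gene's rank-1 hit was not its true ortholog
  hg <- map_top_hits_to_genes(pair$hits, pair$der$genes)
  top1 <- setNames(hg$gene_id[hg$rank == 1L], hg$query_id[hg$rank == 1L])
  decoyed <- names(tp)[!is.na(top1[names(tp)]) & top1[names(tp)] != tp]
  expect_true(any(syn$query_id %in% decoyed))
})

test_that("two unclaimed candidates in the window leave the gene unassigned", {
  # gene order q1..q5 / t1..t5, q3 unassignable by first pass, with two
  # of its hits inside the (t2, t5) window after q2, q5 anchor wide
  qg <- make_genes(paste0("q", 1:5), "c1", "+",
                   start = (0:4) * 100, end = (0:4) * 100 + 90)
  tg <- make_genes(paste0("t", 1:5), "c1", "+",
                   start = (0:4) * 100, end = (0:4) * 100 + 90)
  asn <- new_asn <- data.frame(
    query_id = paste0("q", 1:5),
    target_id = c("t1", "t2", NA, NA, "t5"),
    class = c("syntenic_first_pass", "syntenic_first_pass", "unassigned",
              "unassigned", "syntenic_first_pass"),
    round = c(0L, 0L, NA, NA, 0L), stringsAsFactors = FALSE)
  hit_genes <- data.frame(
    query_id = c("q3", "q3"), rank = c(1L, 2L),
    gene_id = c("t3", "t4"), stringsAsFactors = FALSE)
  out <- rescue_iterative(asn, hit_genes, gene_order(qg), gene_order(tg))
  expect_equal(out$class[out$query_id == "q3"], "unassigned")

  # with a single candidate it is rescued
  out2 <- rescue_iterative(asn, hit_genes[1, ], gene_order(qg),
                           gene_order(tg))
  expect_equal(out2$class[out2$query_id == "q3"], "syntenic_rescued")
  expect_equal(out2$target_id[out2$query_id == "q3"], "t3")
})

test_that("non-syntenic fallback respects claims and overlap", {
  tg <- make_genes(c("t1", "t2"), "c1", "+",
                   start = c(0, 200), end = c(100, 300))
  asn <- data.frame(query_id = c("qa", "qb"),
                    target_id = c("t2", NA),
                    class = c("syntenic_first_pass", "unassigned"),
                    round = c(0L, NA), stringsAsFactors = FALSE)
  out <- assign_non_syntenic(asn, c(qb = "t1"), tg)
  expect_equal(out$class[out$query_id == "qb"], "non_syntenic")
  out2 <- assign_non_syntenic(asn, c(qb = "t2"), tg)
  expect_equal(out2$class[out2$query_id == "qb"], "unassigned")
})

test_that("assignment classes partition query genes with unique targets", {
  pair <- make_pair(31, genes = 50, decoy = 0.3, gene_loss = 0.04)
  asn <- run_ortholog_pipeline(pair$anc$genes, pair$der$genes, pair$hits)
  expect_setequal(asn$query_id, pair$anc$genes$gene_id)
  expect_true(all(asn$class %in% c("syntenic_first_pass",
                                   "syntenic_rescued", "non_syntenic",
                                   "unassigned")))
  tgt <- asn$target_id[!is.na(asn$target_id)]
  expect_equal(anyDuplicated(tgt), 0L)
})

test_that("tRNAs are syntenic iff flankers are syntenic with a query tRNA between", {
  pair <- make_pair(41, n_chrom = 1, genes = 40)
  # plant tRNAs is stochastic; rerun generator with high trna_prob
  anc <- simulate_ancestor(1, 40, 150, rng_seed = 41, trna_prob = 0.5)
  par <- evolution_params(sub_rate = 0.02, rng_seed = 42)
  der <- evolve(anc$genome, anc[c("genes", "trnas")], par)
  hits <- make_hit_table(anc$genes, der$genes, der$truth, rng_seed = 43)
  asn <- run_ortholog_pipeline(anc$genes, der$genes, hits)
  cls <- trna_synteny(anc$trnas, der$trnas, asn, anc$genes, der$genes)
  # evolve kept all tRNAs in place: interior ones are syntenic
  der_interior <- der$trnas$trna_id[
    der$trnas$start > min(der$genes$end) &
      der$trnas$end < max(der$genes$start)]
  expect_true(all(cls[der_interior] == "syntenic"))

  # breaking a flanker's assignment breaks the tRNA's synteny
  g <- der$genes[order(der$genes$start), ]
  if (length(der_interior)) {
    tr <- der$trnas[der$trnas$trna_id == der_interior[1], ]
    left <- g$gene_id[max(which(g$end <= tr$start))]
    asn2 <- asn
    asn2$class[asn2$target_id %in% left] <- "non_syntenic"
    cls2 <- trna_synteny(anc$trnas, der$trnas, asn2, anc$genes, der$genes)
    expect_equal(unname(cls2[der_interior[1]]), "non_syntenic")
  }
})

test_that("prediction classification partitions all genes", {
  pair <- make_pair(51, genes = 40, gene_loss = 0.05)
  asn <- run_ortholog_pipeline(pair$anc$genes, pair$der$genes, pair$hits)
  flags <- setNames(rep(TRUE, nrow(pair$der$genes)),
                    pair$der$genes$gene_id)
  flags[sample(names(flags), 5)] <- FALSE
  cls <- classify_predictions(pair$der$genes, asn, ref_hit_flags = flags)
  expect_equal(nrow(cls), nrow(pair$der$genes))
  counts <- table(cls$class)
  expect_equal(sum(counts), nrow(pair$der$genes))
  expect_true(all(cls$class %in% c("syntenic", "non_syntenic_homolog",
                                   "no_reference_hit")))
  # de novo genes overlapping a prediction are dropped, others kept
  dn <- make_genes(c("d1", "d2"), pair$der$genes$chrom[1], "+",
                   start = c(pair$der$genes$start[1],
                             max(pair$der$genes$end) + 50),
                   end = c(pair$der$genes$end[1],
                           max(pair$der$genes$end) + 200))
  cls2 <- classify_predictions(pair$der$genes, asn, denovo_genes = dn,
                               ref_hit_flags = flags)
  expect_equal(attr(cls2, "n_denovo_overlapping"), 1L)
  expect_true("d2" %in% cls2$gene_id)
  expect_equal(cls2$class[cls2$gene_id == "d2"], "no_reference_hit")
})

test_that("decile enrichment matches the hypergeometric tail exactly", {
  # all flagged genes terminal: p equals the closed-form tail
  chrom_len <- c(c1 = 1000)
  cls <- data.frame(
    gene_id = paste0("g", 1:20), chrom = "c1",
    start = c(seq(0, 90, 10), seq(450, 540, 10)),
    end = c(seq(0, 90, 10), seq(450, 540, 10)) + 8,
    class = rep(c("no_reference_hit", "syntenic"), each = 10),
    stringsAsFactors = FALSE)
  enr <- decile_enrichment(cls, chrom_len)
  k <- 10; n <- 10; K <- 10; N <- 20
  direct <- sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
  expect_equal(enr$p_value, direct, tolerance = 1e-12)
  expect_equal(unname(enr$counts), c(k, n, K, N))

  for (cl in unique(enr$per_decile$class))
    expect_equal(sum(enr$per_decile$fraction[enr$per_decile$class == cl]), 1)

  expect_error(decile_enrichment(cls, c(c1 = 5)), "shorter")
})

test_that("decile enrichment p-values are null-calibrated", {
  set.seed(99)
  chrom_len <- c(c1 = 10000)
  pos <- sort(sample.int(9900, 200))
  pvals <- vapply(1:500, function(i) {
    cls <- data.frame(gene_id = paste0("g", 1:200), chrom = "c1",
                      start = pos, end = pos + 50,
                      class = sample(c("syntenic", "no_reference_hit"),
                                     200, replace = TRUE,
                                     prob = c(0.8, 0.2)),
                      stringsAsFactors = FALSE)
    decile_enrichment(cls, chrom_len)$p_value
  }, numeric(1))
  # discrete p-values are stochastically >= uniform under the null; a KS
  # test against uniform should not reject wildly (alpha 0.01) in the
  # conservative direction
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.4)
})
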