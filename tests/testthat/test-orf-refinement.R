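test_that("fix_stop extends to the first in-frame stop within the window", {
  # CDS missing its stop; "GCTTAA" follows in frame
  genome <- c(c1 = paste0("ATGAAACCC", "GCTTAA", "GGGG"))
  g <- make_genes("g", "c1", "+", start = 0, end = 9,
                  missing_stop = TRUE)
  r <- fix_stop(g[1, ], genome)
  expect_equal(r$status, "corrected")
  expect_equal(r$gene$end, 15)
  cds <- cds_sequence(r$gene, genome)
  expect_equal(substr(cds, nchar(cds) - 2, nchar(cds)), "TAA")

  # no stop within 9 codons
  genome2 <- c(c1 = paste0("ATGAAACCC", strrep("GCA", 12)))
  r2 <- fix_stop(g[1, ], genome2)
  expect_equal(r2$status, "uncorrectable")

  # already ends in a stop: unchanged
  genome3 <- c(c1 = "ATGAAATAAGG")
  g3 <- make_genes("g", "c1", "+", start = 0, end = 9,
                   missing_stop = TRUE)
  expect_equal(fix_stop(g3[1, ], genome3)$status, "unchanged")

  # intron-containing genes untouched
  gi <- make_genes("g", "c1", "+", exons = list(cbind(c(0, 12), c(6, 18))),
                   missing_stop = TRUE)
  expect_equal(fix_stop(gi[1, ], genome2)$status, "unchanged")
})

test_that("fix_start extends to an upstream ATG or truncates past a stop", {
  # ATG 3 codons upstream, no stop between
  genome <- c(c1 = paste0("CC", "ATG", "AAACCC", "GGGTTTCCCTAA", "AA"))
  g <- make_genes("g", "c1", "+", start = 11, end = 23,
                  missing_start = TRUE)
  r <- fix_start(g[1, ], genome)
  expect_equal(r$status, "corrected_extend")
  expect_equal(r$gene$start, 2)
  expect_equal(substr(cds_sequence(r$gene, genome), 1, 3), "ATG")

  # upstream has stop before any ATG; downstream ATG at codon 2
  genome2 <- c(c1 = paste0("CC", "TAA", "AAACCC", "GGGATGCCCTAA", "AA"))
  g2 <- make_genes("g", "c1", "-", start = 0, end = 9,
                   missing_start = TRUE)
  # build an equivalent minus-strand case programmatically
  plus <- paste0("CC", "TAA", "CCC", "GGGATGCCCTAA", "AA")
  genome_m <- c(c1 = revcomp(plus))
  n <- nchar(plus)
  gm <- make_genes("g", "c1", "-", start = n - 20, end = n - 8,
                   missing_start = TRUE)
  rm_ <- fix_start(gm[1, ], genome_m)
  expect_equal(rm_$status, "corrected_truncate")
  expect_equal(substr(cds_sequence(rm_$gene, genome_m), 1, 3), "ATG")

  # already starts with ATG
  g3 <- make_genes("g", "c1", "+", start = 2, end = 11,
                   missing_start = TRUE)
  expect_equal(fix_start(g3[1, ], genome)$status, "unchanged")
})

test_that("boundary fixes agree with an independent oracle on random genes", {
  n_ok_stop <- n_ok_start <- 0L
  n_cases <- 600L
  for (i in seq_len(n_cases)) {
    rf <- random_flagged_gene(i)
    r <- fix_stop(rf$gene, rf$genome)
    o <- oracle_fix_stop(rf$gene, rf$genome)
    expect_equal(r$status, o$status, info = paste("stop case", i))
    if (r$status == "corrected") {
      shift <- if (rf$gene$strand == "+") r$gene$end - rf$gene$end else
        rf$gene$start - r$gene$start
      expect_equal(shift, o$shift, info = paste("stop shift", i))
    }
    n_ok_stop <- n_ok_stop + (r$status == o$status)

    r2 <- fix_start(rf$gene, rf$genome)
    o2 <- oracle_fix_start(rf$gene, rf$genome)
    expect_equal(r2$status, o2$status, info = paste("start case", i))
    n_ok_start <- n_ok_start + (r2$status == o2$status)
  }
  expect_equal(n_ok_stop, n_cases)
  expect_equal(n_ok_start, n_cases)
})

test_that("refine_boundaries accounts for every flagged gene", {
  run <- simulate_ancestor(1, 20, 120, rng_seed = 77)
  genes <- run$genes
  # truncate some genes so flags are real
  set.seed(78)
  idx <- sample.int(nrow(genes), 8)
  for (i in idx[1:4]) {   # chop the stop codon
    if (genes$strand[i] == "+") genes$end[i] <- genes$end[i] - 3
    else genes$start[i] <- genes$start[i] + 3
    genes$exons[[i]] <- matrix(c(genes$start[i], genes$end[i]), 1)
    genes$missing_stop[i] <- TRUE
  }
  for (i in idx[5:8]) {   # chop the start codon
    if (genes$strand[i] == "+") genes$start[i] <- genes$start[i] + 3
    else genes$end[i] <- genes$end[i] - 3
    genes$exons[[i]] <- matrix(c(genes$start[i], genes$end[i]), 1)
    genes$missing_start[i] <- TRUE
  }
  res <- refine_boundaries(genes, run$genome)
  expect_equal(nrow(res$status), 8L)
  expect_true(all(res$status$status %in%
                    c("corrected", "corrected_extend", "corrected_truncate",
                      "uncorrectable", "unchanged")))
  # stop-chopped genes are restored to a stop-terminated CDS
  stop_fixed <- res$status$gene_id[res$status$op == "stop" &
                                     res$status$status == "corrected"]
  for (gid in stop_fixed) {
    g <- res$genes[res$genes$gene_id == gid, ]
    cds <- cds_sequence(g[1, ], run$genome)
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("frameshift detection flags internal out-of-frame gaps only", {
  qseq <- "ATGAAACCCGGGTTTAGC"
  # 1-bp deletion mid-CDS in the target
  tseq <- paste0(substr(qseq, 1, 8), substr(qseq, 10, 18))
  qg <- make_genes("q", "c1", "+", start = 0, end = nchar(qseq))
  tg <- make_genes("t", "c1", "+", start = 0, end = nchar(tseq))
  ev <- detect_frameshifts(qg[1, ], tg[1, ], c(c1 = qseq), c(c1 = tseq))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$indel_len, -1L)

  # 3-bp in-frame gap: no event
  t3 <- paste0(substr(qseq, 1, 8), substr(qseq, 12, 18))
  tg3 <- make_genes("t", "c1", "+", start = 0, end = nchar(t3))
  ev3 <- detect_frameshifts(qg[1, ], tg3[1, ], c(c1 = qseq), c(c1 = t3))
  expect_equal(nrow(ev3), 0L)
})

test_that("homopolymer context reports the longer run across both species", {
  qseq <- "ATGCCTAAAAAACGGTTTCCGGAAGCC"
  tseq <- paste0(substr(qseq, 1, 8), substr(qseq, 10, 27))  # deletes one A
  qg <- make_genes("q", "c1", "+", start = 0, end = nchar(qseq))
  tg <- make_genes("t", "c1", "+", start = 0, end = nchar(tseq))
  ev <- detect_frameshifts(qg[1, ], tg[1, ], c(c1 = qseq), c(c1 = tseq))
  ev <- homopolymer_context(ev, c(c1 = tseq))
  expect_equal(nrow(ev), 1L)
  expect_true(ev$in_homopolymer)
  expect_equal(ev$hp_base, "A")
  expect_equal(ev$hp_len, 6)  # query run is the longer one

  # event between unrelated bases is not a homopolymer
  q2 <- "ATGACGTACGTACGTACGTTAG"
  t2 <- paste0(substr(q2, 1, 10), substr(q2, 12, 22))
  qg2 <- make_genes("q", "c1", "+", start = 0, end = nchar(q2))
  tg2 <- make_genes("t", "c1", "+", start = 0, end = nchar(t2))
  ev2 <- detect_frameshifts(qg2[1, ], tg2[1, ], c(c1 = q2), c(c1 = t2))
  ev2 <- homopolymer_context(ev2, c(c1 = t2))
  if (nrow(ev2)) expect_false(any(ev2$in_homopolymer))
})

test_that("frameshift reports aggregate per gene and per event", {
  ev <- data.frame(
    gene_id = c("g1", "g1", "g2"), chrom = "c1", pos = c(10, 50, 70),
    indel_len = c(1L, -1L, 1L), strand = "+",
    q_run_base = "A", q_run_len = 4L,
    in_homopolymer = c(TRUE, TRUE, FALSE),
    hp_base = c("A", "T", NA), hp_len = c(4L, 5L, 0L),
    stringsAsFactors = FALSE)
  rep <- frameshift_report(list(draft = ev, polished = ev[0, ]))
  expect_equal(rep$summary$n_orfs_frameshift, c(2L, 0L))
  expect_equal(rep$summary$n_events, c(3L, 0L))
  bb <- rep$by_base[rep$by_base$version == "draft", ]
  expect_equal(bb$count[bb$base == "A"], 1L)
  expect_equal(bb$count[bb$base == "T"], 1L)
  expect_equal(sum(rep$by_base$count[rep$by_base$version == "polished"]), 0L)
})
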