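#' Simulate a ranked protein-to-genome hit table
#'
#' Emulates the failure mode of similarity-ranked annotation transfer: the
#' true ortholog always receives a hit at its true locus, but with
#' probability `decoy_prob` a higher-scoring decoy hit at a random other
#' gene's locus outranks it, so that only gene-order context can recover
#' the correct assignment.  Lost query genes receive only spurious hits.
#'
#' @param query_genes,target_genes [make_genes()] tables of the two genomes.
#' @param truth Truth table from [evolve()] (`pairs`, `lost`).
#' @param decoy_prob Probability of a decoy outranking the true hit.
#' @param score_jitter Relative standard deviation of score noise.
#' @param rank_swap_prob Probability of swapping the scores of a random
#'   adjacent rank pair within a query.
#' @param noise_hits Mean number of additional low-scoring random hits per
#'   query (Poisson).
#' @param rng_seed Integer seed.
#' @param max_rank Hits beyond this rank are dropped.
#' @return A ranked hit table (see [rank_hits()]).
#' @export
make_hit_table <- function(query_genes, target_genes, truth,
                           decoy_prob = 0, score_jitter = 0,
                           rank_swap_prob = 0, noise_hits = 1.5,
                           rng_seed = 1L, max_rank = 10L) {
  for (p in c(decoy_prob, score_jitter, rank_swap_prob))
    if (p < 0 || p > 1) stop("noise probabilities must lie in [0, 1]")
  set.seed(rng_seed)
  tg <- target_genes
  rows <- list()
  add <- function(qid, g_row, score) {
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = qid, chrom = g_row$chrom, start = g_row$start,
      end = g_row$end, strand = g_row$strand, score = score,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(query_genes))) {
    qid <- query_genes$gene_id[i]
    qlen <- query_genes$end[i] - query_genes$start[i]
    base <- 2 * qlen
    tid <- unname(truth$pairs[qid])
    scores_here <- numeric(0)
    if (!is.na(tid) && length(tid)) {
      ti <- match(tid, tg$gene_id)
      s_true <- base * (1 + rnorm(1, 0, score_jitter))
      add(qid, tg[ti, ], s_true)
      scores_here <- s_true
      if (runif(1) < decoy_prob) {
        di <- sample(setdiff(seq_len(nrow(tg)), ti), 1L)
        add(qid, tg[di, ], s_true * 1.05 + 1)
      }
      n_noise <- rpois(1L, noise_hits)
    } else {
      ti <- NA_integer_
      n_noise <- rpois(1L, 0.5)
    }
    if (n_noise > 0L) {
      pool <- setdiff(seq_len(nrow(tg)), ti)
      ni <- sample(pool, min(n_noise, length(pool)))
      for (j in ni) add(qid, tg[j, ], base * runif(1, 0.2, 0.8))
    }
  }
  hits <- do.call(rbind, rows)
  hits <- rank_hits(hits)
  if (rank_swap_prob > 0) {
    for (qid in unique(hits$query_id)) {
      idx <- which(hits$query_id == qid)
      if (length(idx) >= 2L && runif(1) < rank_swap_prob) {
        k <- sample.int(length(idx) - 1L, 1L)
        sw <- hits$score[idx[c(k, k + 1L)]]
        hits$score[idx[c(k, k + 1L)]] <- rev(sw)
      }
    }
    hits$rank <- NULL
    hits <- rank_hits(hits)
  }
  hits <- hits[hits$rank <= max_rank, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Plant assembly errors into a genome
#'
#' Introduces `n_snp` single-base substitutions and `n_indel` +-1 bp
#' homopolymer miscounts (at runs of length `>= min_run`) at mutually
#' separated sites, emulating pyrosequencing errors in a draft assembly.
#'
#' @param genome Named character vector (the true sequence).
#' @param n_snp,n_indel Number of substitutions / homopolymer indels.
#' @param min_run Minimum homopolymer run length for indel sites.
#' @param rng_seed Integer seed.
#' @param min_gap Minimum separation (bp) between planted error sites.
#' @return A list with `genome` (the erroneous sequence) and `edits`, a
#'   data.frame describing each planted error in true-genome coordinates
#'   (`chrom`, `pos`, `etype` in `{sub, ins_err, del_err}`, `true_base`,
#'   `err_base`, `run_len`, `delta`).
#' @export
plant_assembly_errors <- function(genome, n_snp, n_indel, min_run = 3L,
                                  rng_seed = 1L, min_gap = 6L) {
  set.seed(rng_seed)
  chroms <- names(genome)
  lens <- nchar(genome)
  # candidate indel sites: homopolymer runs >= min_run
  run_sites <- list()
  for (ch in chroms) {
    s <- strsplit(genome[[ch]], "")[[1L]]
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_run & r$values %in% DNA_BASES
    if (any(keep))
      run_sites[[ch]] <- data.frame(chrom = ch, pos = starts[keep] - 1L,
                                    base = r$values[keep],
                                    run_len = r$lengths[keep],
                                    stringsAsFactors = FALSE)
  }
  run_sites <- do.call(rbind, run_sites)
  if (is.null(run_sites) || nrow(run_sites) < n_indel)
    stop("genome has fewer than n_indel homopolymer runs >= min_run")
  idx <- sample.int(nrow(run_sites), nrow(run_sites))
  chosen <- list(); occupied <- list()
  is_free <- function(ch, lo, hi) {
    occ <- occupied[[ch]]
    is.null(occ) || !any(occ$lo <= hi & occ$hi >= lo)
  }
  claim <- function(ch, lo, hi) {
    occupied[[ch]] <<- rbind(occupied[[ch]], data.frame(lo = lo, hi = hi))
  }
  n_got <- 0L
  for (i in idx) {
    if (n_got == n_indel) break
    r <- run_sites[i, ]
    lo <- r$pos - min_gap; hi <- r$pos + r$run_len + min_gap
    if (!is_free(r$chrom, lo, hi)) next
    claim(r$chrom, lo, hi)
    delta <- sample(c(-1L, 1L), 1L)
    chosen[[length(chosen) + 1L]] <- data.frame(
      chrom = r$chrom, pos = r$pos,
      etype = if (delta == 1L) "ins_err" else "del_err",
      true_base = r$base, err_base = r$base, run_len = r$run_len,
      delta = delta, stringsAsFactors = FALSE)
    n_got <- n_got + 1L
  }
  if (n_got < n_indel) stop("could not place ", n_indel, " separated indels")
  # SNP sites
  n_got <- 0L; guard <- 0L
  while (n_got < n_snp) {
    guard <- guard + 1L
    if (guard > 50L * n_snp + 1000L) stop("could not place separated SNPs")
    ch <- sample(chroms, 1L, prob = lens)
    p <- sample.int(lens[[ch]], 1L) - 1L
    if (!is_free(ch, p - min_gap, p + min_gap)) next
    b <- substr(genome[[ch]], p + 1L, p + 1L)
    if (!(b %in% DNA_BASES)) next
    claim(ch, p - min_gap, p + min_gap)
    chosen[[length(chosen) + 1L]] <- data.frame(
      chrom = ch, pos = p, etype = "sub", true_base = b,
      err_base = sample(setdiff(DNA_BASES, b), 1L), run_len = NA_integer_,
      delta = 0L, stringsAsFactors = FALSE)
    n_got <- n_got + 1L
  }
  edits <- do.call(rbind, chosen)
  edits <- edits[order(edits$chrom, edits$pos), , drop = FALSE]
  rownames(edits) <- NULL
  # apply errors right to left
  err <- genome
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    s <- err[[ch]]
    for (i in rev(seq_len(nrow(e)))) {
      p <- e$pos[i]
      s <- switch(e$etype[i],
        sub = paste0(substr(s, 1L, p), e$err_base[i],
                     substr(s, p + 2L, nchar(s))),
        ins_err = paste0(substr(s, 1L, p), e$err_base[i],
                         substr(s, p + 1L, nchar(s))),
        del_err = paste0(substr(s, 1L, p), substr(s, p + 2L, nchar(s))))
    }
    err[[ch]] <- s
  }
  list(genome = err, edits = edits)
}

#' Variant calls that restore planted assembly errors
#'
#' Converts a [plant_assembly_errors()] edit table into calls expressed in
#' the erroneous genome's coordinates whose application restores the true
#' sequence: planted substitutions become SNP calls, extra-base errors
#' become 1-bp deletions and missing-base errors 1-bp insertions.
#'
#' @param edits Edit table from [plant_assembly_errors()].
#' @param support Support values recycled across calls (default all 0.9).
#' @return A variant table (see [make_variants()]) with an extra
#'   `run_len` column carrying the true homopolymer run length of indel
#'   calls (used by truth-diff callers to recognise applied calls).
#' @export
restoring_calls <- function(edits, support = 0.9) {
  out <- list()
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    shift <- cumsum(c(0L, e$delta[-nrow(e)]))
    pos_err <- e$pos + shift
    ref <- ifelse(e$etype == "sub", e$err_base,
           ifelse(e$etype == "ins_err", e$err_base, ""))
    alt <- ifelse(e$etype == "sub", e$true_base,
           ifelse(e$etype == "ins_err", "", e$true_base))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, pos = pos_err, ref = ref, alt = alt,
      run_len = e$run_len, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  calls <- make_variants(df$chrom, df$pos, df$ref, df$alt,
                         rep_len(support, nrow(df)))
  calls$run_len <- df$run_len
  calls
}

#' Truth-diff variant caller
#'
#' Returns a pure function of a genome that emits the remaining
#' truth-restoring calls: an empty set once the genome equals the truth,
#' otherwise the calls from [restoring_calls()] that are still applicable
#' (SNPs whose erroneous base is still present; indels whose local
#' homopolymer run length still differs from the true run length).
#'
#' @param true_genome The error-free genome.
#' @param edits Edit table from [plant_assembly_errors()].
#' @param support Support values for the emitted calls (fixed at
#'   construction so the caller is deterministic).
#' @return A function `genome -> variant table`.
#' @export
make_truth_caller <- function(true_genome, edits, support = 0.9) {
  calls <- restoring_calls(edits, support)
  run_len_at <- function(s, pos, base) {
    n <- nchar(s)
    if (pos < 0L || pos >= n) return(0L)
    if (substr(s, pos + 1L, pos + 1L) != base) return(0L)
    lo <- pos; hi <- pos
    while (lo > 0L && substr(s, lo, lo) == base) lo <- lo - 1L
    while (hi + 1L < n && substr(s, hi + 2L, hi + 2L) == base) hi <- hi + 1L
    hi - lo + 1L
  }
  function(genome) {
    if (identical(unname(genome[names(true_genome)]),
                  unname(true_genome)))
      return(calls[0L, , drop = FALSE])
    keep <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      s <- genome[[calls$chrom[i]]]
      p <- calls$pos[i]
      keep[i] <- switch(calls$vtype[i],
        SNP = substr(s, p + 1L, p + 1L) == calls$ref[i],
        DEL = run_len_at(s, p, calls$ref[i]) == calls$run_len[i] + 1L,
        INS = run_len_at(s, p, calls$alt[i]) == calls$run_len[i] - 1L ||
              (calls$run_len[i] == 1L && run_len_at(s, p, calls$alt[i]) == 0L))
    }
    calls[keep, , drop = FALSE]
  }
}

#' Simulate a depth track and a noisy variant-call set
#'
#' Every planted error yields a truth-restoring call with Beta-distributed
#' support centred near 0.9; additional false calls are emitted at
#' `error_frac` per base with support below 0.6.  The depth track is
#' Poisson around `mean_depth`, scaled by copy number over any supplied
#' `cn_regions`.
#'
#' @param true_genome The error-free genome (named character vector).
#' @param erroneous_genome The genome carrying planted errors.
#' @param edits Edit table from [plant_assembly_errors()]; may be omitted
#'   when the two genomes are equal-length (SNP-only differences are then
#'   diffed directly) or identical.
#' @param mean_depth Mean read depth.
#' @param error_frac False-call rate per base.
#' @param rng_seed Integer seed.
#' @param cn_regions Optional data.frame `chrom, start, end, copy` of
#'   copy-number regions (0-based half-open).
#' @return A list with `depth` (named list of integer vectors over the
#'   erroneous genome) and `calls` (a variant table).
#' @export
simulate_depth_and_variants <- function(true_genome, erroneous_genome,
                                        edits = NULL, mean_depth = 50,
                                        error_frac = 0, rng_seed = 1L,
                                        cn_regions = NULL) {
  set.seed(rng_seed)
  if (is.null(edits)) {
    if (identical(unname(true_genome), unname(erroneous_genome[names(true_genome)]))) {
      calls <- make_variants(character(), numeric(), character(),
                             character(), numeric())
    } else if (all(nchar(true_genome) ==
                   nchar(erroneous_genome[names(true_genome)]))) {
      rows <- list()
      for (ch in names(true_genome)) {
        a <- strsplit(true_genome[[ch]], "")[[1L]]
        b <- strsplit(erroneous_genome[[ch]], "")[[1L]]
        d <- which(a != b)
        if (length(d)) rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = d - 1L, ref = b[d], alt = a[d],
          stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      calls <- make_variants(df$chrom, df$pos, df$ref, df$alt,
                             rep(0.9, nrow(df)))
    } else {
      stop("genomes differ in length; supply the edit table")
    }
  } else {
    calls <- restoring_calls(edits)
    calls$run_len <- NULL
  }
  if (nrow(calls))
    calls$support <- rbeta(nrow(calls), 18, 2)
  # false calls with sub-threshold support
  if (error_frac > 0) {
    rows <- list()
    for (ch in names(erroneous_genome)) {
      n <- rpois(1L, error_frac * nchar(erroneous_genome[[ch]]))
      if (n == 0L) next
      p <- sample.int(nchar(erroneous_genome[[ch]]), n) - 1L
      b <- substring(erroneous_genome[[ch]], p + 1L, p + 1L)
      ok <- b %in% DNA_BASES
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = p[ok], ref = b[ok],
        alt = vapply(b[ok], function(x) sample(setdiff(DNA_BASES, x), 1L), ""),
        support = runif(sum(ok), 0.05, 0.599), stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      fc <- do.call(rbind, rows)
      fcalls <- make_variants(fc$chrom, fc$pos, fc$ref, fc$alt, fc$support)
      calls <- rbind(calls, fcalls)
    }
  }
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  depth <- lapply(names(erroneous_genome), function(ch) {
    n <- nchar(erroneous_genome[[ch]])
    copy <- rep(1, n)
    if (!is.null(cn_regions)) {
      cr <- cn_regions[cn_regions$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(cr)))
        copy[(cr$start[i] + 1L):cr$end[i]] <- cr$copy[i]
    }
    rpois(n, mean_depth * copy)
  })
  names(depth) <- names(erroneous_genome)
  list(depth = depth, calls = calls)
}
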