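#' Globally align two coding sequences
#'
#' Thin wrapper around [Biostrings::pairwiseAlignment()] with parameters
#' chosen so that point substitutions never open gaps, keeping single-base
#' indels as isolated gap columns.
#'
#' @param query_seq,target_seq DNA strings in coding orientation.
#' @return List with aligned strings `q` and `t` (equal length, gaps `-`).
#' @export
align_cds_pair <- function(query_seq, target_seq) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query_seq), Biostrings::DNAString(target_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 3)
  list(q = as.character(Biostrings::alignedPattern(pa)),
       t = as.character(Biostrings::alignedSubject(pa)))
}

# single-base runs touching position `at` (1-based) in `s`: one
# (base, len) pair per distinct run covering at-1, at or at+1
runs_touching <- function(s, at) {
  ch <- strsplit(s, "")[[1L]]
  out <- list()
  seen <- integer(0)
  for (p in unique(pmax(1L, pmin(length(ch), c(at - 1L, at, at + 1L))))) {
    b <- ch[p]
    if (!(b %in% DNA_BASES)) next
    lo <- p; hi <- p
    while (lo > 1L && ch[lo - 1L] == b) lo <- lo - 1L
    while (hi < length(ch) && ch[hi + 1L] == b) hi <- hi + 1L
    if (lo %in% seen) next
    seen <- c(seen, lo)
    out[[length(out) + 1L]] <- list(base = b, len = hi - lo + 1L)
  }
  out
}

# longest run of one character touching position `at` (1-based) in `s`
run_at <- function(s, at) {
  rs <- runs_touching(s, at)
  if (!length(rs)) return(list(base = "", len = 0L))
  rs[[which.max(vapply(rs, `[[`, 0L, "len"))]]
}

#' Detect frameshift-causing indels in an aligned gene pair
#'
#' Every internal alignment gap whose length is not divisible by 3 emits
#' one event at its target-genome coordinate; gaps touching the alignment
#' termini are ignored as boundary artifacts.  Positive `indel_len` means
#' bases present in the target but not the query (insertion), negative
#' the reverse (deletion).
#'
#' @param query_gene,target_gene Single rows of [make_genes()] tables.
#' @param query_genome,target_genome Named character vectors.
#' @param alignment Optional precomputed [align_cds_pair()] result.
#' @return Data.frame of events: `gene_id`, `chrom`, `pos`, `indel_len`,
#'   `strand`, plus query-side homopolymer context (`q_run_base`,
#'   `q_run_len`) consumed by [homopolymer_context()].
#' @export
detect_frameshifts <- function(query_gene, target_gene, query_genome,
                               target_genome, alignment = NULL) {
  if (is.null(alignment)) {
    qseq <- cds_sequence(query_gene, query_genome)
    tseq <- cds_sequence(target_gene, target_genome)
    alignment <- align_cds_pair(qseq, tseq)
  }
  q <- strsplit(alignment$q, "")[[1L]]
  t <- strsplit(alignment$t, "")[[1L]]
  n <- length(q)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      pos = numeric(), indel_len = integer(),
                      strand = character(), q_run_base = character(),
                      q_run_len = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  gap_runs <- function(is_gap) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & starts > 1L & ends < n  # internal gaps only
    data.frame(start = starts[keep], len = r$lengths[keep])
  }
  t_off <- cumsum(t != "-")  # target bases consumed up to each column
  rows <- list()
  emit <- function(col, len, sign) {
    if (len %% 3L == 0L) return()
    # local 0-based target offset of the gap (first inserted base, or the
    # base following a deletion)
    p_local <- if (col == 1L) 0L else t_off[col - 1L]
    pos <- if (target_gene$strand == "+") target_gene$start + p_local
           else target_gene$end - 1L - p_local
    qr <- run_at(alignment$q, col - 1L)
    if (qr$len == 0L) qr <- run_at(alignment$q, col + len)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = target_gene$gene_id, chrom = target_gene$chrom,
      pos = pos, indel_len = sign * len, strand = target_gene$strand,
      q_run_base = qr$base, q_run_len = qr$len, stringsAsFactors = FALSE)
  }
  gq <- gap_runs(q == "-")
  for (i in seq_len(nrow(gq))) emit(gq$start[i], gq$len[i], +1L)
  gt <- gap_runs(t == "-")
  for (i in seq_len(nrow(gt))) emit(gt$start[i], gt$len[i], -1L)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$pos), , drop = FALSE]
}

#' Attribute frameshift events to homopolymer runs
#'
#' Examines the maximal single-base run covering or abutting each event
#' position in the target genome and, when its base corresponds, the
#' query-side run captured at detection time; the longer of the two is
#' reported.  Events whose run reaches `min_run` are flagged
#' `in_homopolymer`.
#'
#' @param events Event table from [detect_frameshifts()].
#' @param target_genome Named character vector.
#' @param min_run Minimum run length counting as a homopolymer.
#' @return The event table with added `in_homopolymer`, `hp_base`,
#'   `hp_len` columns.
#' @export
homopolymer_context <- function(events, target_genome, min_run = 3L) {
  n <- nrow(events)
  events$in_homopolymer <- logical(n)
  events$hp_base <- NA_character_
  events$hp_len <- 0L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(n)) {
    s <- target_genome[[events$chrom[i]]]
    cands <- runs_touching(s, events$pos[i] + 1L)
    qb <- events$q_run_base[i]
    # query context was read in coding orientation
    qb_genomic <- if (nzchar(qb) && events$strand[i] == "-") comp[[qb]]
                  else qb
    # effective length per candidate: the longer of the two species' runs
    # (miscounting changes the run length between the sequences)
    eff <- vapply(cands, function(r) {
      if (nzchar(qb_genomic) && identical(r$base, qb_genomic))
        max(r$len, events$q_run_len[i]) else as.numeric(r$len)
    }, numeric(1))
    if (!length(cands)) {
      hp_base <- ""; hp_len <- 0L
    } else {
      k <- which.max(eff)
      hp_base <- cands[[k]]$base; hp_len <- eff[k]
    }
    if (hp_len >= min_run && nzchar(hp_base)) {
      events$in_homopolymer[i] <- TRUE
      events$hp_base[i] <- hp_base
      events$hp_len[i] <- hp_len
    } else {
      events$hp_len[i] <- hp_len
    }
  }
  events
}

#' Frameshift census across orthologous gene pairs
#'
#' Aligns each assigned ortholog pair and collects frameshift events with
#' homopolymer context.
#'
#' @param assignments Assignment table (syntenic and non-syntenic classes
#'   are all used).
#' @param query_genes,target_genes [make_genes()] tables.
#' @param query_genome,target_genome Named character vectors.
#' @param min_run Minimum homopolymer run length.
#' @return Event table over all pairs.
#' @export
frameshift_census <- function(assignments, query_genes, target_genes,
                              query_genome, target_genome, min_run = 3L) {
  asn <- assignments[!is.na(assignments$target_id), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(asn))) {
    qg <- query_genes[query_genes$gene_id == asn$query_id[i], ]
    tg <- target_genes[target_genes$gene_id == asn$target_id[i], ]
    if (!nrow(qg) || !nrow(tg)) next
    ev <- detect_frameshifts(qg[1, ], tg[1, ], query_genome, target_genome)
    if (nrow(ev)) out[[length(out) + 1L]] <- ev
  }
  ev <- if (length(out)) do.call(rbind, out) else
    detect_frameshifts(NULL, NULL, NULL, NULL,
                       alignment = list(q = "", t = ""))
  homopolymer_context(ev, target_genome, min_run)
}

#' Summarise frameshift events per assembly version
#'
#' A gene counts once in the ORF total however many events it carries;
#' the base and run-length histograms count every homopolymer event.
#'
#' @param events_by_version Named list of event tables (one per assembly
#'   version, e.g. before and after polishing).
#' @param len_bins Breaks for homopolymer length bins; the last bin is
#'   open-ended.
#' @return List with `summary` (per version: `n_orfs_frameshift`,
#'   `n_events`), `by_base` and `by_length` histograms.
#' @export
frameshift_report <- function(events_by_version,
                              len_bins = c(3:9, Inf)) {
  versions <- names(events_by_version)
  summary <- do.call(rbind, lapply(versions, function(v) {
    ev <- events_by_version[[v]]
    data.frame(version = v,
               n_orfs_frameshift = length(unique(ev$gene_id)),
               n_events = nrow(ev), stringsAsFactors = FALSE)
  }))
  by_base <- do.call(rbind, lapply(versions, function(v) {
    ev <- events_by_version[[v]]
    ev <- ev[ev$in_homopolymer, , drop = FALSE]
    data.frame(version = v, base = DNA_BASES,
               count = as.integer(table(factor(ev$hp_base,
                                               levels = DNA_BASES))),
               stringsAsFactors = FALSE)
  }))
  by_length <- do.call(rbind, lapply(versions, function(v) {
    ev <- events_by_version[[v]]
    ev <- ev[ev$in_homopolymer, , drop = FALSE]
    bin <- cut(ev$hp_len, breaks = c(len_bins[1L] - 1L, len_bins),
               labels = FALSE)
    data.frame(version = v, hp_len = len_bins,
               count = as.integer(table(factor(bin,
                                               levels = seq_along(len_bins)))),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, by_base = by_base, by_length = by_length)
}
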