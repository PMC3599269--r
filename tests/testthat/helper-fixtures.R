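# shared fixtures and independent oracles for the test suite

# small ancestor/descendant pair with noisy hits; returns everything the
# ortholog pipeline consumes
make_pair <- function(seed, n_chrom = 2L, genes = 60L, sub_rate = 0.03,
                      hp_indel_rate = 0, gene_loss = 0, n_inv = 0L,
                      n_tra = 0L, decoy = 0, a_bias = 2) {
  anc <- simulate_ancestor(n_chrom, genes, 150, rng_seed = seed)
  par <- evolution_params(sub_rate = sub_rate,
                          hp_indel_rate = hp_indel_rate,
                          gene_loss_prob = gene_loss,
                          n_inversions = n_inv, n_translocations = n_tra,
                          a_bias = a_bias, rng_seed = seed + 1000L)
  der <- evolve(anc$genome, anc[c("genes", "trnas")], par)
  hits <- make_hit_table(anc$genes, der$genes, der$truth,
                         decoy_prob = decoy, score_jitter = 0.02,
                         rng_seed = seed + 2000L)
  list(anc = anc, der = der, hits = hits)
}

# exhaustive-candidate N50 oracle: try every contig length as L
n50_oracle <- function(lens, min_len = 0) {
  lens <- lens[lens >= min_len]
  if (!length(lens)) return(0)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= sum(lens) / 2) return(L)
  min(lens)
}

# strsplit-based gap oracle, independent of the regex implementation
gap_oracle <- function(s) {
  r <- rle(strsplit(s, "")[[1]] == "N")
  r$lengths[r$values]
}

# independent boundary-fix oracles working directly on the coding-strand
# sequence (extracted once, scanned by codon index)
oracle_fix_stop <- function(gene, genome, window = 9L) {
  chrom <- genome[[gene$chrom]]
  len <- gene$end - gene$start
  cds <- substr(chrom, gene$start + 1, gene$end)
  if (gene$strand == "-") cds <- revcomp(cds)
  stops <- c("TAA", "TAG", "TGA")
  last <- substr(cds, len - 2, len)
  if (last %in% stops) return(list(status = "unchanged", shift = 0L))
  down <- if (gene$strand == "+")
    substr(chrom, gene$end + 1, nchar(chrom)) else
    revcomp(substr(chrom, 1, gene$start))
  for (d in seq_len(window)) {
    if (3 * d > nchar(down)) return(list(status = "uncorrectable"))
    cod <- substr(down, 3 * d - 2, 3 * d)
    if (cod %in% stops) return(list(status = "corrected", shift = 3L * d))
  }
  list(status = "uncorrectable")
}

oracle_fix_start <- function(gene, genome, window = 9L) {
  chrom <- genome[[gene$chrom]]
  cds <- substr(chrom, gene$start + 1, gene$end)
  if (gene$strand == "-") cds <- revcomp(cds)
  stops <- c("TAA", "TAG", "TGA")
  if (substr(cds, 1, 3) == "ATG")
    return(list(status = "unchanged", shift = 0L))
  up <- if (gene$strand == "+")
    substr(chrom, 1, gene$start) else
    revcomp(substr(chrom, gene$end + 1, nchar(chrom)))
  saw_stop <- FALSE
  for (d in seq_len(window)) {
    if (3 * d > nchar(up)) break
    cod <- substr(up, nchar(up) - 3 * d + 1, nchar(up) - 3 * d + 3)
    if (cod %in% stops) { saw_stop <- TRUE; break }
    if (cod == "ATG")
      return(list(status = "corrected_extend", shift = -3L * d))
  }
  if (saw_stop) {
    n_codons <- nchar(cds) %/% 3
    for (d in seq_len(min(window, max(0L, n_codons - 2L)))) {
      if (substr(cds, 3 * d + 1, 3 * d + 3) == "ATG")
        return(list(status = "corrected_truncate", shift = 3L * d))
    }
  }
  list(status = "uncorrectable")
}

# brute-force tree likelihood: sum over all internal-state assignments
brute_force_loglik <- function(aln, tree, model) {
  pd <- alignment_patterns(aln, model)
  S <- length(model$states)
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1L]
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(po$edge)),
              function(k) transition_matrix(model, po$edge.length[k]))
  internal <- (ntip + 1L):nn
  grid <- as.matrix(do.call(expand.grid, rep(list(1:S), length(internal))))
  total <- 0
  for (site in seq_len(pd$n_sites)) {
    col <- pd$pat[, pd$site2pat[site]]
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(nn)
      st[internal] <- grid[g, ]
      p <- model$freqs[st[root]]
      for (k in seq_len(nrow(po$edge))) {
        par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
        if (chi <= ntip) {
          obs <- col[match(tree$tip.label[chi], pd$taxa)]
          pc <- if (obs == 0L) 1 else P[[k]][st[par], obs]
        } else pc <- P[[k]][st[par], st[chi]]
        p <- p * pc
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# truth-containment helper for rearrangement events
bp_contained <- function(events, genome_side, chrom, pos) {
  any(vapply(events, function(ev) {
    bp <- ev$breakpoints
    if (is.null(bp)) return(FALSE)
    bp <- bp[bp$genome == genome_side, , drop = FALSE]
    any((is.na(bp$start) | bp$start <= pos) &
        (is.na(bp$end) | bp$end >= pos) & bp$chrom == chrom)
  }, logical(1)))
}

# random single-exon gene inside a fresh random chromosome; the CDS is a
# random window so start/stop flags are typically violated
random_flagged_gene <- function(seed) {
  set.seed(seed)
  chrom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  len <- 3L * sample(4:40, 1L)
  start <- sample.int(400L - len - 60L, 1L) + 29L
  strand <- sample(c("+", "-"), 1L)
  g <- make_genes("g", "c1", strand, start = start, end = start + len,
                  missing_start = TRUE, missing_stop = TRUE)
  list(gene = g[1L, ], genome = c(c1 = chrom))
}
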