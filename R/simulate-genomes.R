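rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Evolution parameters for the synthetic descendant genome
#'
#' The defaults emulate a sensu-stricto-scale divergence: a few percent
#' substitutions per site, homopolymer-biased single-base indels with an
#' excess in A/T runs (the pyrosequencing error regime), occasional gene
#' loss, and large-scale rearrangements restricted to inversions and
#' reciprocal translocations with intergenic breakpoints.
#'
#' @param sub_rate Substitutions per site.
#' @param hp_indel_rate Probability that a homopolymer run of length
#'   `>= min_run` receives a +-1 bp indel.
#' @param gene_loss_prob Per-gene probability of loss.
#' @param n_inversions,n_translocations Counts of planted rearrangements.
#' @param a_bias Multiplier on `hp_indel_rate` for A/T runs.
#' @param min_run Minimum homopolymer run length eligible for an indel.
#' @param rng_seed Integer seed.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(sub_rate = 0.03, hp_indel_rate = 0,
                             gene_loss_prob = 0, n_inversions = 0L,
                             n_translocations = 0L, a_bias = 2,
                             min_run = 3L, rng_seed = 1L) {
  for (r in c(sub_rate, hp_indel_rate, gene_loss_prob))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (n_inversions < 0L || n_translocations < 0L) stop("counts must be >= 0")
  structure(list(sub_rate = sub_rate, hp_indel_rate = hp_indel_rate,
                 gene_loss_prob = gene_loss_prob,
                 n_inversions = as.integer(n_inversions),
                 n_translocations = as.integer(n_translocations),
                 a_bias = a_bias, min_run = as.integer(min_run),
                 rng_seed = as.integer(rng_seed)),
            class = "evolution_params")
}

# one intergenic spacer with planted homopolymer runs and (optionally) a tRNA
make_spacer <- function(mean_len, with_trna = FALSE) {
  len <- 30L + rpois(1L, max(0L, as.integer(mean_len) - 30L))
  if (with_trna) len <- len + 110L
  s <- strsplit(rand_dna(len), "")[[1L]]
  n_runs <- 1L + rpois(1L, 1L)
  used <- rep(FALSE, len)
  trna <- NULL
  if (with_trna) {
    tlen <- sample(70:90, 1L)
    tstart <- sample.int(len - tlen - 10L, 1L) + 5L
    used[tstart:(tstart + tlen - 1L)] <- TRUE
    trna <- list(start = tstart - 1L, len = tlen,
                 strand = sample(c("+", "-"), 1L),
                 isotype = sample(LETTERS[1:20], 1L))
  }
  for (k in seq_len(n_runs)) {
    rl <- min(12L, 3L + rgeom(1L, 0.4))
    for (try in 1:20) {
      p <- sample.int(len - rl - 1L, 1L)
      idx <- p:(p + rl - 1L)
      # keep a planted run from touching a used region or an equal flank base
      if (any(used[max(1L, p - 1L):min(len, p + rl)])) next
      b <- sample(DNA_BASES, 1L)
      s[idx] <- b
      if (p > 1L && s[p - 1L] == b) s[p - 1L] <- sample(setdiff(DNA_BASES, b), 1L)
      if (p + rl <= len && s[p + rl] == b)
        s[p + rl] <- sample(setdiff(DNA_BASES, b), 1L)
      used[idx] <- TRUE
      break
    }
  }
  list(seq = paste(s, collapse = ""), trna = trna)
}

#' Simulate a gene-dense ancestral genome
#'
#' Chromosomes are alternating runs of intergenic spacers and single-exon
#' ORFs (`ATG ... TAA/TAG/TGA`, random strand).  Spacers carry planted
#' homopolymer runs (length 3-12, geometric) and, with probability
#' `trna_prob`, a tRNA model.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param genes_per_chrom Genes per chromosome (>= 3).
#' @param intergenic_len_mean Mean spacer length in bp.
#' @param rng_seed Integer seed; the output is byte-identical for equal
#'   seeds.
#' @param codon_range Range of CDS lengths in codons (including start and
#'   stop).
#' @param trna_prob Probability that a spacer carries a tRNA.
#' @return A list with `genome` (named character vector), `genes`
#'   ([make_genes()] table) and `trnas` ([make_trnas()] table).
#' @export
simulate_ancestor <- function(n_chrom, genes_per_chrom,
                              intergenic_len_mean = 150,
                              rng_seed = 1L,
                              codon_range = c(60L, 150L),
                              trna_prob = 0.05) {
  if (n_chrom < 1L) stop("n_chrom must be >= 1")
  if (genes_per_chrom < 3L) stop("genes_per_chrom must be >= 3")
  if (intergenic_len_mean < 30) stop("intergenic_len_mean too small (< 30)")
  set.seed(rng_seed)
  genome <- character(0)
  gid <- tid <- 0L
  g_rows <- list(); t_rows <- list()
  for (ci in seq_len(n_chrom)) {
    chrom <- sprintf("chr%d", ci)
    parts <- character(0); pos <- 0L
    add_spacer <- function(pos, parts) {
      sp <- make_spacer(intergenic_len_mean, runif(1) < trna_prob)
      if (!is.null(sp$trna)) {
        tid <<- tid + 1L
        t_rows[[length(t_rows) + 1L]] <<- data.frame(
          trna_id = sprintf("trna%04d", tid), chrom = chrom,
          strand = sp$trna$strand, start = pos + sp$trna$start,
          end = pos + sp$trna$start + sp$trna$len,
          isotype = sp$trna$isotype, stringsAsFactors = FALSE)
      }
      list(pos = pos + nchar(sp$seq), parts = c(parts, sp$seq))
    }
    st <- add_spacer(pos, parts); pos <- st$pos; parts <- st$parts
    for (gi in seq_len(genes_per_chrom)) {
      gid <- gid + 1L
      nc <- sample(codon_range[1L]:codon_range[2L], 1L)
      cds <- paste0("ATG",
                    paste(sample(NONSTOP_CODONS, nc - 2L, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1L))
      strand <- sample(c("+", "-"), 1L)
      oriented <- if (strand == "+") cds else revcomp(cds)
      g_rows[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid), chrom = chrom, strand = strand,
        start = pos, end = pos + nchar(oriented), stringsAsFactors = FALSE)
      parts <- c(parts, oriented); pos <- pos + nchar(oriented)
      st <- add_spacer(pos, parts); pos <- st$pos; parts <- st$parts
    }
    genome[chrom] <- paste(parts, collapse = "")
  }
  gdf <- do.call(rbind, g_rows)
  genes <- make_genes(gdf$gene_id, gdf$chrom, gdf$strand,
                      start = gdf$start, end = gdf$end)
  trnas <- if (length(t_rows)) do.call(rbind, t_rows) else
    make_trnas(character(), character(), character(), numeric(),
               numeric() + 1, character())
  list(genome = genome, genes = genes, trnas = trnas)
}
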