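#' Syntenic classification of tRNAs
#'
#' A target tRNA is syntenic iff its two flanking protein-coding genes are
#' syntenic-class assignments and at least one query tRNA lies between
#' those genes' partners in the query genome.
#'
#' @param query_trnas,target_trnas [make_trnas()] tables.
#' @param assignments Assignment table (see [run_ortholog_pipeline()]).
#' @param query_genes,target_genes [make_genes()] tables.
#' @return Named character vector, target tRNA id -> `"syntenic"` or
#'   `"non_syntenic"`.
#' @export
trna_synteny <- function(query_trnas, target_trnas, assignments,
                        query_genes, target_genes) {
  syn <- assignments[assignments$class %in%
                       c("syntenic_first_pass", "syntenic_rescued"), ,
                     drop = FALSE]
  q_of_t <- setNames(syn$query_id, syn$target_id)
  out <- setNames(rep("non_syntenic", nrow(target_trnas)),
                  target_trnas$trna_id)
  for (i in seq_len(nrow(target_trnas))) {
    tr <- target_trnas[i, ]
    g <- target_genes[target_genes$chrom == tr$chrom, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    left <- g[g$end <= tr$start, , drop = FALSE]
    right <- g[g$start >= tr$end, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    lg <- left$gene_id[nrow(left)]; rg <- right$gene_id[1L]
    lq <- q_of_t[lg]; rq <- q_of_t[rg]
    if (is.na(lq) || is.na(rq)) next
    p1 <- query_genes[query_genes$gene_id == lq, ]
    p2 <- query_genes[query_genes$gene_id == rq, ]
    if (p1$chrom != p2$chrom) next
    lo <- min(p1$end, p2$end); hi <- max(p1$start, p2$start)
    between <- query_trnas$chrom == p1$chrom &
      query_trnas$start >= lo & query_trnas$end <= hi
    if (any(between)) out[tr$trna_id] <- "syntenic"
  }
  out
}

#' Classify target gene predictions
#'
#' Partitions homology-based predictions plus de-novo predictions into
#' `syntenic` (target of a syntenic-class assignment),
#' `non_syntenic_homolog` (has a reference hit but no conserved gene
#' order) and `no_reference_hit`.  De-novo predictions whose exons overlap
#' a homology-based prediction by >= 1 bp on either strand are dropped as
#' redundant (counted in attribute `n_denovo_overlapping`).
#'
#' @param target_genes Homology-based [make_genes()] table.
#' @param assignments Assignment table.
#' @param denovo_genes Optional de-novo [make_genes()] table.
#' @param ref_hit_flags Named logical vector, gene id -> has a hit in the
#'   reference proteome (a precomputed similarity table, not a search).
#'   Genes absent from the vector default to `FALSE`.
#' @return Data.frame `gene_id`, `chrom`, `start`, `end`, `class`.
#' @export
classify_predictions <- function(target_genes, assignments,
                                 denovo_genes = NULL,
                                 ref_hit_flags = NULL) {
  syn_targets <- assignments$target_id[
    assignments$class %in% c("syntenic_first_pass", "syntenic_rescued")]
  all_g <- target_genes[, c("gene_id", "chrom", "start", "end")]
  n_overlap <- 0L
  if (!is.null(denovo_genes) && nrow(denovo_genes)) {
    tr <- IRanges::IRanges(target_genes$start + 1L, target_genes$end)
    dr <- IRanges::IRanges(denovo_genes$start + 1L, denovo_genes$end)
    ov <- IRanges::findOverlaps(dr, tr)
    same <- denovo_genes$chrom[S4Vectors::queryHits(ov)] ==
      target_genes$chrom[S4Vectors::subjectHits(ov)]
    bad <- unique(S4Vectors::queryHits(ov)[same])
    n_overlap <- length(bad)
    keep <- setdiff(seq_len(nrow(denovo_genes)), bad)
    if (length(keep))
      all_g <- rbind(all_g,
                     denovo_genes[keep, c("gene_id", "chrom", "start", "end")])
  }
  has_hit <- rep(FALSE, nrow(all_g))
  if (!is.null(ref_hit_flags)) {
    m <- match(all_g$gene_id, names(ref_hit_flags))
    has_hit[!is.na(m)] <- unname(ref_hit_flags[m[!is.na(m)]])
  }
  cls <- ifelse(all_g$gene_id %in% syn_targets, "syntenic",
         ifelse(has_hit, "non_syntenic_homolog", "no_reference_hit"))
  out <- cbind(all_g, class = cls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_denovo_overlapping") <- n_overlap
  out
}

#' Terminal-decile enrichment of non-syntenic and novel genes
#'
#' Each gene is binned by midpoint into equal-length bins of its
#' chromosome (`1 / decile_fraction` bins; deciles by default).
#' Enrichment of `non_syntenic_homolog` and `no_reference_hit` genes in
#' the first and last bin is tested one-sided by the hypergeometric upper
#' tail (drawing `k` flagged of `n` terminal genes from `K` flagged of
#' `N` total).
#'
#' @param classified Output of [classify_predictions()].
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param decile_fraction Terminal fraction per chromosome end.
#' @return List with `per_decile` (per-class gene fractions by bin, each
#'   class summing to 1), `p_value`, and the hypergeometric counts
#'   (`k`, `n`, `K`, `N`).
#' @export
decile_enrichment <- function(classified, chrom_lengths,
                              decile_fraction = 0.1) {
  n_bins <- as.integer(round(1 / decile_fraction))
  if (any(chrom_lengths < n_bins))
    stop("chromosome shorter than ", n_bins, " bp")
  len <- chrom_lengths[classified$chrom]
  if (any(is.na(len))) stop("gene on a chromosome without a length")
  mid <- (classified$start + classified$end) / 2
  bin <- pmin(n_bins, floor(mid / (len / n_bins)) + 1L)
  flagged <- classified$class %in% c("non_syntenic_homolog",
                                     "no_reference_hit")
  terminal <- bin == 1L | bin == n_bins
  k <- sum(flagged & terminal); n <- sum(terminal)
  K <- sum(flagged); N <- nrow(classified)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  per_decile <- do.call(rbind, lapply(unique(classified$class), function(cl) {
    sel <- classified$class == cl
    data.frame(class = cl, decile = seq_len(n_bins),
               fraction = tabulate(bin[sel], n_bins) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  list(per_decile = per_decile, p_value = p,
       counts = c(k = k, n = n, K = K, N = N))
}
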