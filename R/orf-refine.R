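# codon at displacement d (in codons) downstream of the CDS end, read in
# coding orientation; NULL when it would run off the chromosome
codon_after_end <- function(gene, chrom_seq, d) {
  if (gene$strand == "+") {
    a <- gene$end + 3 * (d - 1)
    if (a + 3 > nchar(chrom_seq)) return(NULL)
    substr(chrom_seq, a + 1, a + 3)
  } else {
    a <- gene$start - 3 * d
    if (a < 0) return(NULL)
    revcomp(substr(chrom_seq, a + 1, a + 3))
  }
}

# codon at displacement d (in codons) upstream of the CDS start
codon_before_start <- function(gene, chrom_seq, d) {
  if (gene$strand == "+") {
    a <- gene$start - 3 * d
    if (a < 0) return(NULL)
    substr(chrom_seq, a + 1, a + 3)
  } else {
    a <- gene$end + 3 * (d - 1)
    if (a + 3 > nchar(chrom_seq)) return(NULL)
    revcomp(substr(chrom_seq, a + 1, a + 3))
  }
}

# codon index d (0-based) of the CDS itself, in coding orientation
codon_inside <- function(gene, chrom_seq, d) {
  if (gene$strand == "+") {
    a <- gene$start + 3 * d
    substr(chrom_seq, a + 1, a + 3)
  } else {
    a <- gene$end - 3 * (d + 1)
    revcomp(substr(chrom_seq, a + 1, a + 3))
  }
}

#' Correct a missing stop codon by bounded downstream extension
#'
#' Scans in-frame codons downstream of the current CDS end, up to
#' `window` codons; the first stop codon found extends the gene to
#' include it.  Intron-containing genes are left untouched, as are genes
#' that already terminate with a stop.
#'
#' @param gene One row of a [make_genes()] table.
#' @param genome Named character vector of chromosome sequences.
#' @param window Maximum displacement in codons.
#' @return List with `gene` (possibly modified row) and `status` in
#'   `{"corrected", "uncorrectable", "unchanged"}`.
#' @export
fix_stop <- function(gene, genome, window = 9L) {
  if (isTRUE(gene$has_intron))
    return(list(gene = gene, status = "unchanged"))
  chrom_seq <- genome[[gene$chrom]]
  last <- codon_inside(gene, chrom_seq,
                       (gene$end - gene$start) %/% 3 - 1L)
  if (last %in% STOP_CODONS) {
    gene$missing_stop <- FALSE
    return(list(gene = gene, status = "unchanged"))
  }
  for (d in seq_len(window)) {
    cod <- codon_after_end(gene, chrom_seq, d)
    if (is.null(cod)) return(list(gene = gene, status = "uncorrectable"))
    if (cod %in% STOP_CODONS) {
      if (gene$strand == "+") gene$end <- gene$end + 3 * d
      else gene$start <- gene$start - 3 * d
      gene$exons[[1L]] <- matrix(c(gene$start, gene$end), nrow = 1L)
      gene$missing_stop <- FALSE
      return(list(gene = gene, status = "corrected"))
    }
  }
  list(gene = gene, status = "uncorrectable")
}

#' Correct a missing start codon by bounded extension or truncation
#'
#' Searches upstream in-frame codons up to `window` codons for the first
#' `ATG` with no intervening in-frame stop (extension); if a stop occurs
#' upstream before any `ATG`, searches downstream inside the CDS up to
#' `window` codons for an `ATG` to truncate to.  Intron-containing genes
#' and genes already starting with `ATG` are left untouched.
#'
#' @inheritParams fix_stop
#' @return List with `gene` and `status` in `{"corrected_extend",
#'   "corrected_truncate", "uncorrectable", "unchanged"}`.
#' @export
fix_start <- function(gene, genome, window = 9L) {
  if (isTRUE(gene$has_intron))
    return(list(gene = gene, status = "unchanged"))
  chrom_seq <- genome[[gene$chrom]]
  if (codon_inside(gene, chrom_seq, 0L) == "ATG") {
    gene$missing_start <- FALSE
    return(list(gene = gene, status = "unchanged"))
  }
  saw_stop <- FALSE
  for (d in seq_len(window)) {
    cod <- codon_before_start(gene, chrom_seq, d)
    if (is.null(cod)) break  # chromosome boundary
    if (cod %in% STOP_CODONS) { saw_stop <- TRUE; break }
    if (cod == "ATG") {
      if (gene$strand == "+") gene$start <- gene$start - 3 * d
      else gene$end <- gene$end + 3 * d
      gene$exons[[1L]] <- matrix(c(gene$start, gene$end), nrow = 1L)
      gene$missing_start <- FALSE
      return(list(gene = gene, status = "corrected_extend"))
    }
  }
  if (saw_stop) {
    n_codons <- (gene$end - gene$start) %/% 3
    for (d in seq_len(min(window, max(0L, n_codons - 2L)))) {
      if (codon_inside(gene, chrom_seq, d) == "ATG") {
        if (gene$strand == "+") gene$start <- gene$start + 3 * d
        else gene$end <- gene$end - 3 * d
        gene$exons[[1L]] <- matrix(c(gene$start, gene$end), nrow = 1L)
        gene$missing_start <- FALSE
        return(list(gene = gene, status = "corrected_truncate"))
      }
    }
  }
  list(gene = gene, status = "uncorrectable")
}

#' Batch boundary refinement
#'
#' Applies [fix_stop()] to all genes flagged `missing_stop` and
#' [fix_start()] to all genes flagged `missing_start`.
#'
#' @param genes A [make_genes()] table.
#' @param genome Named character vector.
#' @param config A [pipeline_config()] supplying the windows.
#' @return List with `genes` (refined table) and `status`, a data.frame
#'   of per-gene statuses for each operation attempted.
#' @export
refine_boundaries <- function(genes, genome, config = pipeline_config()) {
  rows <- list()
  put <- function(i, g) {
    genes$start[i] <<- g$start
    genes$end[i] <<- g$end
    genes$exons[[i]] <<- g$exons[[1L]]
    genes$missing_start[i] <<- g$missing_start
    genes$missing_stop[i] <<- g$missing_stop
  }
  for (i in seq_len(nrow(genes))) {
    if (isTRUE(genes$missing_stop[i])) {
      r <- fix_stop(genes[i, ], genome, config$stop_window_codons)
      put(i, r$gene)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], op = "stop", status = r$status,
        stringsAsFactors = FALSE)
    }
    if (isTRUE(genes$missing_start[i])) {
      r <- fix_start(genes[i, ], genome, config$start_window_codons)
      put(i, r$gene)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], op = "start", status = r$status,
        stringsAsFactors = FALSE)
    }
  }
  status <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), op = character(),
               status = character(), stringsAsFactors = FALSE)
  list(genes = genes, status = status)
}
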