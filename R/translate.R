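#' Extract the spliced CDS sequence of a gene
#'
#' Exon sequences are concatenated in genomic order; minus-strand genes are
#' reverse-complemented so the result always reads 5' to 3'.
#'
#' @param gene One row of a [make_genes()] table.
#' @param genome Named character vector of chromosome sequences.
#' @return The CDS as a character string.
#' @export
cds_sequence <- function(gene, genome) {
  chrom <- genome[[gene$chrom]]
  if (is.null(chrom)) stop("chromosome not in genome: ", gene$chrom)
  ex <- gene$exons[[1L]]
  if (max(ex[, 2L]) > nchar(chrom)) stop("exon beyond chromosome end")
  s <- paste(substring(chrom, ex[, 1L] + 1, ex[, 2L]), collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Translate a coding sequence
#'
#' Spliced, strand-aware translation under the standard nuclear code.  A
#' trailing stop codon is dropped; internal stops are retained as `*`.  A
#' CDS whose length is not divisible by 3 is translated over its longest
#' in-frame prefix and the result carries attribute `partial = TRUE`.
#'
#' @param gene One row of a [make_genes()] table.
#' @param genome Named character vector of chromosome sequences.
#' @return Protein sequence as a character string.
#' @export
#' @examples
#' g <- make_genes("g1", "c1", "+", start = 0, end = 9)
#' translate_cds(g[1, ], c(c1 = "ATGGCTTAA"))
translate_cds <- function(gene, genome) {
  translate_dna(cds_sequence(gene, genome))
}

#' @rdname translate_cds
#' @param cds A CDS string read 5' to 3'.
#' @export
translate_dna <- function(cds) {
  n <- nchar(cds)
  partial <- (n %% 3L) != 0L
  n <- n - (n %% 3L)
  if (n < 3L) return(structure("", partial = partial))
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  structure(paste(aa, collapse = ""), partial = partial)
}
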