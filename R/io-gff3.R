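#' Construct a gene table
#'
#' Genes are held in a plain `data.frame` with one row per gene and an
#' `exons` list-column of two-column matrices holding `[start, end)`
#' intervals in 0-based half-open coordinates.  `start`/`end` give the
#' genomic span (first exon start, last exon end).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome identifier per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param exons List of numeric matrices (n x 2) of exon intervals, or
#'   `NULL` for single-exon genes described by `start`/`end`.
#' @param start,end Genomic span, 0-based half-open (used when `exons`
#'   is `NULL`).
#' @param missing_start,missing_stop Logical boundary flags.
#' @return A `data.frame` of class `c("gene_table", "data.frame")`.
#' @export
make_genes <- function(gene_id, chrom, strand, exons = NULL,
                       start = NULL, end = NULL,
                       missing_start = FALSE, missing_stop = FALSE) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  if (is.null(exons)) {
    stopifnot(!is.null(start), !is.null(end))
    exons <- mapply(function(s, e) matrix(c(s, e), nrow = 1L),
                    start, end, SIMPLIFY = FALSE)
  }
  stopifnot(length(exons) == n)
  exons <- lapply(exons, function(m) {
    m <- matrix(as.numeric(m), ncol = 2L)
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[, 2L] <= m[, 1L])) stop("exon with end <= start")
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
      stop("overlapping exons in one gene")
    m
  })
  cds_len <- vapply(exons, function(m) sum(m[, 2L] - m[, 1L]), numeric(1))
  if (any(cds_len < 3)) stop("CDS length < 3")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = vapply(exons, function(m) m[1L, 1L], numeric(1)),
                   end = vapply(exons, function(m) m[nrow(m), 2L], numeric(1)),
                   n_exons = vapply(exons, nrow, integer(1)),
                   has_intron = vapply(exons, nrow, integer(1)) > 1L,
                   missing_start = rep_len(missing_start, n),
                   missing_stop = rep_len(missing_stop, n),
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$exons <- I(exons)
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Construct a tRNA table
#'
#' @param trna_id Unique identifiers.
#' @param chrom,strand,start,end Location (0-based half-open).
#' @param isotype One-letter amino-acid isotype.
#' @return A `data.frame`, one row per tRNA.
#' @export
make_trnas <- function(trna_id, chrom, strand, start, end, isotype) {
  stopifnot(all(end > start))
  data.frame(trna_id = as.character(trna_id), chrom = as.character(chrom),
             strand = as.character(strand), start = as.numeric(start),
             end = as.numeric(end), isotype = as.character(isotype),
             stringsAsFactors = FALSE)
}

#' Read gene and tRNA models from GFF3
#'
#' Converts 1-based inclusive GFF3 coordinates to the internal 0-based
#' half-open convention (`start_internal = start_gff - 1`, end unchanged).
#' `CDS` features are grouped by their `Parent` attribute; a parent with
#' more than one CDS becomes a multi-exon gene with `has_intron = TRUE`.
#' Boundary flags are read from a `flags` attribute
#' (`missing_start`/`missing_stop`, comma-separated) on the parent feature.
#'
#' @param path Path to a GFF3 file.
#' @return A list with elements `genes` (a [make_genes()] table) and
#'   `trnas` (a [make_trnas()] table, possibly empty).
#' @seealso [write_gff3()]
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  cds <- gr[type == "CDS"]
  genes <- NULL
  if (length(cds)) {
    parents <- S4Vectors::mcols(cds)$Parent
    pl <- if (is.null(parents)) rep(list(character()), length(cds))
          else as.list(parents)
    if (any(lengths(pl) == 0L))
      stop("CDS feature without a Parent attribute in ", path)
    parent_id <- vapply(pl, `[[`, character(1), 1L)
    ord <- order(parent_id, GenomicRanges::start(cds))
    cds <- cds[ord]; parent_id <- parent_id[ord]
    exn <- split(data.frame(s = GenomicRanges::start(cds) - 1,
                            e = GenomicRanges::end(cds)), parent_id)
    ids <- names(exn)
    first <- cds[!duplicated(parent_id)]
    first <- first[match(ids, parent_id[!duplicated(parent_id)])]
    # per-parent flags from the parent feature when present
    par_md <- gr[type %in% c("mRNA", "gene")]
    flag_of <- function(id) {
      hit <- par_md[which(S4Vectors::mcols(par_md)$ID == id)]
      fl <- if (length(hit)) S4Vectors::mcols(hit)$flags[1L] else NA
      if (is.null(fl) || is.na(fl)) "" else as.character(fl)
    }
    flags <- vapply(ids, flag_of, character(1))
    genes <- make_genes(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(first)),
      strand = as.character(BiocGenerics::strand(first)),
      exons = lapply(exn, function(d) cbind(d$s, d$e)),
      missing_start = grepl("missing_start", flags),
      missing_stop = grepl("missing_stop", flags))
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    class(genes) <- c("gene_table", "data.frame")
  } else {
    genes <- empty_genes()
  }

  tr <- gr[type == "tRNA"]
  trnas <- if (length(tr)) {
    iso <- S4Vectors::mcols(tr)$isotype
    make_trnas(trna_id = as.character(S4Vectors::mcols(tr)$ID),
               chrom = as.character(GenomicRanges::seqnames(tr)),
               strand = as.character(BiocGenerics::strand(tr)),
               start = GenomicRanges::start(tr) - 1,
               end = GenomicRanges::end(tr),
               isotype = if (is.null(iso)) NA_character_ else
                 as.character(iso))
  } else {
    make_trnas(character(), character(), character(), numeric(),
               numeric() + 1, character())
  }
  list(genes = genes, trnas = trnas)
}

empty_genes <- function() {
  df <- data.frame(gene_id = character(), chrom = character(),
                   strand = character(), start = numeric(), end = numeric(),
                   n_exons = integer(), has_intron = logical(),
                   missing_start = logical(), missing_stop = logical(),
                   stringsAsFactors = FALSE)
  df$exons <- I(list())
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Write gene and tRNA models to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open intervals become
#' 1-based inclusive GFF3 lines (one `mRNA` parent plus one `CDS` line per
#' exon for each gene; one `tRNA` line per tRNA).
#'
#' @param genes A [make_genes()] table.
#' @param path Output path.
#' @param trnas Optional [make_trnas()] table.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, trnas = NULL, source = "arborator") {
  rows <- list()
  esc <- function(x) x  # ids are plain tokens by construction
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    fl <- c(if (isTRUE(g$missing_start)) "missing_start",
            if (isTRUE(g$missing_stop)) "missing_stop")
    attr_m <- paste0("ID=", esc(g$gene_id),
                     if (length(fl)) paste0(";flags=", paste(fl, collapse = ",")))
    rows[[length(rows) + 1L]] <-
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, source, as.integer(g$start) + 1L, as.integer(g$end),
              g$strand, attr_m)
    ex <- g$exons[[1L]]
    for (j in seq_len(nrow(ex)))
      rows[[length(rows) + 1L]] <-
        sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                g$chrom, source, as.integer(ex[j, 1L]) + 1L,
                as.integer(ex[j, 2L]), g$strand, esc(g$gene_id), j,
                esc(g$gene_id))
  }
  if (!is.null(trnas) && nrow(trnas)) {
    for (i in seq_len(nrow(trnas))) {
      t <- trnas[i, ]
      rows[[length(rows) + 1L]] <-
        sprintf("%s\t%s\ttRNA\t%d\t%d\t.\t%s\t.\tID=%s;isotype=%s",
                t$chrom, source, as.integer(t$start) + 1L, as.integer(t$end),
                t$strand, esc(t$trna_id), t$isotype)
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}
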