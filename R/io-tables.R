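#' Rank protein-to-genome hits per query
#'
#' Ranks are assigned within each query by strictly non-increasing score;
#' score ties are broken deterministically by `(chrom, start)` ascending.
#'
#' @param hits A `data.frame` with columns `query_id`, `chrom`, `start`,
#'   `end`, `strand`, `score` (0-based half-open intervals).
#' @return The same table with an integer `rank` column, sorted by
#'   `(query_id, rank)`.
#' @export
rank_hits <- function(hits) {
  need <- c("query_id", "chrom", "start", "end", "strand", "score")
  if (!all(need %in% names(hits)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  if (nrow(hits) == 0L) {
    hits$rank <- integer(0)
    return(hits)
  }
  key <- do.call(paste, c(hits[need], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate hit rows (identical on all fields)")
  ord <- order(hits$query_id, -hits$score, hits$chrom, hits$start)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- as.integer(unlist(lapply(
    split(seq_len(nrow(hits)), hits$query_id)[unique(hits$query_id)],
    seq_along), use.names = FALSE))
  rownames(hits) <- NULL
  hits
}

#' Read a ranked hit table from TSV
#'
#' Columns: `query_id`, `chrom`, `start`, `end`, `strand`, `score`
#' (a stand-in for a ranked aligner report).  Ranks are recomputed from the
#' scores on read, so the stored rank column (if any) is ignored.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A ranked hit table (see [rank_hits()]).
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$rank <- NULL
  rank_hits(df)
}

#' @rdname read_hits_tsv
#' @param hits A ranked hit table.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write variant calls (VCF-like TSV)
#'
#' Columns `chrom`, `pos` (0-based), `ref`, `alt`, `support`.  `ref` is
#' empty for insertions and `alt` empty for deletions; the `vtype` column
#' (`SNP`, `INS`, `DEL`) is derived from the alleles.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `vtype`, `support`.
#' @export
read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(ref = "character", alt = "character"))
  df$ref[is.na(df$ref)] <- ""
  df$alt[is.na(df$alt)] <- ""
  make_variants(df$chrom, df$pos, df$ref, df$alt, df$support)
}

#' @rdname read_variants_tsv
#' @param calls A variant table.
#' @export
write_variants_tsv <- function(calls, path) {
  write.table(calls[, c("chrom", "pos", "ref", "alt", "support")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a variant-call table
#'
#' @param chrom,pos Location of the call (0-based position).
#' @param ref,alt Reference and alternate alleles; `ref = ""` denotes an
#'   insertion before `pos`, `alt = ""` a deletion starting at `pos`.
#' @param support Fraction of alignment data supporting the call.
#' @return A `data.frame` with a derived `vtype` column.
#' @export
make_variants <- function(chrom, pos, ref, alt, support) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  vtype <- ifelse(nchar(ref) == 0L, "INS",
           ifelse(nchar(alt) == 0L, "DEL", "SNP"))
  bad <- vtype == "SNP" & (nchar(ref) != 1L | nchar(alt) != 1L)
  if (any(bad))
    stop("SNP calls must have single-base ref and alt alleles")
  if (any(support < 0 | support > 1)) stop("support must lie in [0, 1]")
  data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
             ref = ref, alt = alt, vtype = vtype,
             support = as.numeric(support), stringsAsFactors = FALSE)
}

#' Read / write growth curves (TSV)
#'
#' Long-format table with columns `strain`, `condition`, `replicate`,
#' `time_min`, `od`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `data.frame` in long format.
#' @export
read_growth_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_growth_tsv
#' @param curves A growth-curve table.
#' @export
write_growth_tsv <- function(curves, path) {
  write.table(curves, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
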