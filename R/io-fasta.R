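#' Read a genome from FASTA
#'
#' Sequences are uppercased and validated against the strict alphabet
#' `{A, C, G, T, N}`: RNA (`U`) and IUPAC ambiguity codes other than `N`
#' are rejected, as are empty records and duplicate sequence names.  Gap
#' runs are represented as runs of `N`.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase DNA string per sequence.
#' @seealso [write_fasta()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtn"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs))))
    stop("FASTA record with empty header in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record in ", path, ": ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGTN]", "", seqs[bad]), "")))
    stop("disallowed characters in ", paste(names(seqs)[bad], collapse = ", "),
         ": ", paste(ch, collapse = ""),
         " (only A, C, G, T, N are accepted)")
  }
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  set <- Biostrings::DNAStringSet(toupper(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param seq A single DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
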