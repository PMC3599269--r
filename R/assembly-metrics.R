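#' Assembly contig metrics
#'
#' Contigs shorter than `min_len` are excluded.  N50 is the length `L`
#' such that contigs of length `>= L` sum to at least half the filtered
#' total, computed by descending cumulative sum.
#'
#' @param contigs Character vector of contig sequences, or numeric vector
#'   of contig lengths.
#' @param min_len Minimum contig length retained.
#' @return List with `n_contigs`, `total_len`, `mean_len`, `max_len`,
#'   `n50`.
#' @export
#' @examples
#' assembly_metrics(c(2, 2, 2, 3, 3, 4, 8, 8), min_len = 0)$n50
assembly_metrics <- function(contigs, min_len = 500L) {
  len <- if (is.character(contigs)) nchar(contigs) else as.numeric(contigs)
  len <- len[len >= min_len]
  if (!length(len))
    return(list(n_contigs = 0L, total_len = 0, mean_len = 0, max_len = 0,
                n50 = 0))
  sl <- sort(len, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= sum(sl) / 2)[1L]]
  list(n_contigs = length(len), total_len = sum(len),
       mean_len = mean(len), max_len = max(len), n50 = n50)
}

#' Gap statistics of scaffold sequences
#'
#' Gaps are maximal runs of `N`.
#'
#' @param scaffolds Named or unnamed character vector of sequences.
#' @return List with `n_gaps`, `mean_gap`, `min_gap`, `max_gap` (zeros
#'   when there are no gaps).
#' @export
#' @examples
#' gap_stats("ACGTNNNACGTNA")
gap_stats <- function(scaffolds) {
  lens <- unlist(lapply(scaffolds, function(s) {
    m <- gregexpr("N+", s)[[1L]]
    if (m[1L] == -1L) integer(0) else attr(m, "match.length")
  }), use.names = FALSE)
  if (!length(lens))
    return(list(n_gaps = 0L, mean_gap = 0, min_gap = 0, max_gap = 0))
  list(n_gaps = length(lens), mean_gap = mean(lens),
       min_gap = min(lens), max_gap = max(lens))
}

#' Log2 coverage ratio in fixed windows
#'
#' Depth is averaged in non-overlapping windows along each chromosome
#' (a final short window is kept when at least half the window size,
#' otherwise merged into the previous one), divided by the genome-wide
#' mean depth, and log2-transformed.
#'
#' @param depth Named list of per-base depth vectors.
#' @param window Window size in bp.
#' @return Data.frame `chrom`, `win_start`, `win_end`, `depth_mean`,
#'   `log2_ratio` (0-based half-open windows).
#' @export
coverage_windows <- function(depth, window = 1000L) {
  genome_mean <- mean(unlist(depth, use.names = FALSE))
  out <- list()
  for (ch in names(depth)) {
    d <- depth[[ch]]
    n <- length(d)
    starts <- seq(0L, n - 1L, by = window)
    ends <- pmin(starts + window, n)
    if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)])
        < window / 2) {
      # merge the short tail into the previous window
      ends[length(ends) - 1L] <- ends[length(ends)]
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
    mu <- vapply(seq_along(starts),
                 function(i) mean(d[(starts[i] + 1L):ends[i]]), numeric(1))
    out[[ch]] <- data.frame(chrom = ch, win_start = starts, win_end = ends,
                            depth_mean = mu,
                            log2_ratio = log2(mu / genome_mean),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
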