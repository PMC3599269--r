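#' Apply supported variant calls to a genome
#'
#' Calls with `support >= min_support` and `vtype` in `vtypes` are applied
#' per chromosome from highest coordinate to lowest, so earlier
#' coordinates never shift under indels.  A call whose `ref` allele does
#' not match the genome is rejected and logged, never silently applied.
#' Overlapping accepted calls keep the higher-support one (ties by
#' position).
#'
#' @param genome Named character vector.
#' @param calls Variant table (see [make_variants()]).
#' @param min_support Minimum support fraction.
#' @param vtypes Which variant types to apply this phase.
#' @return List with `genome` (edited), `applied` and `rejected` call
#'   tables (`rejected` carries a `reason` column).
#' @export
apply_variants <- function(genome, calls, min_support = 0.6,
                           vtypes = c("SNP", "INS", "DEL")) {
  keep_cols <- c("chrom", "pos", "ref", "alt", "vtype", "support")
  calls <- calls[, keep_cols, drop = FALSE]
  rejected <- cbind(calls[0L, , drop = FALSE],
                    reason = character(0), stringsAsFactors = FALSE)
  reject <- function(rows, reason) {
    if (nrow(rows))
      rejected <<- rbind(rejected, cbind(rows, reason = reason,
                                         stringsAsFactors = FALSE))
  }
  sel <- calls$vtype %in% vtypes
  pool <- calls[sel, , drop = FALSE]
  low <- pool$support < min_support
  reject(pool[low, , drop = FALSE], "support")
  pool <- pool[!low, , drop = FALSE]
  # overlap resolution: interval [pos, pos + nchar(ref)) (insertions are
  # points); higher support wins, ties by position
  if (nrow(pool)) {
    pool$lo <- pool$pos
    pool$hi <- pool$pos + pmax(nchar(pool$ref), 1L) - 1L
    pool <- pool[order(pool$chrom, -pool$support, pool$pos), , drop = FALSE]
    keep <- logical(nrow(pool))
    occ <- list()
    for (i in seq_len(nrow(pool))) {
      ch <- pool$chrom[i]
      o <- occ[[ch]]
      clash <- !is.null(o) && any(o$lo <= pool$hi[i] & o$hi >= pool$lo[i])
      if (!clash) {
        keep[i] <- TRUE
        occ[[ch]] <- rbind(o, data.frame(lo = pool$lo[i], hi = pool$hi[i]))
      }
    }
    reject(pool[!keep, keep_cols, drop = FALSE], "overlap")
    pool <- pool[keep, , drop = FALSE]
  }
  applied <- calls[0L, , drop = FALSE]
  if (nrow(pool)) {
    pool <- pool[order(pool$chrom, -pool$pos), , drop = FALSE]
    ok <- logical(nrow(pool))
    for (ch in unique(pool$chrom)) {
      rows <- which(pool$chrom == ch)
      s <- genome[[ch]]
      if (is.null(s)) next
      # right-to-left: build the edited sequence from unchanged pieces
      pieces <- character(0)
      tail_from <- nchar(s) + 1L
      for (i in rows) {
        p <- pool$pos[i]; ref <- pool$ref[i]
        cur <- substr(s, p + 1L, p + nchar(ref))
        if (nchar(ref) > 0L && !identical(cur, ref)) next
        ok[i] <- TRUE
        pieces <- c(pool$alt[i],
                    substring(s, p + nchar(ref) + 1L, tail_from - 1L),
                    pieces)
        tail_from <- p + 1L
      }
      genome[[ch]] <- paste0(substr(s, 1L, tail_from - 1L),
                             paste(pieces, collapse = ""))
    }
    no_chrom <- !(pool$chrom %in% names(genome))
    reject(pool[no_chrom, keep_cols, drop = FALSE], "chrom")
    reject(pool[!ok & !no_chrom, keep_cols, drop = FALSE], "ref_mismatch")
    applied <- pool[ok, keep_cols, drop = FALSE]
  }
  rownames(applied) <- rownames(rejected) <- NULL
  list(genome = genome, applied = applied, rejected = rejected)
}

#' Iterative SNP-then-indel assembly polishing
#'
#' Each round calls variants on the current genome, filters and applies
#' the SNPs, re-calls on the updated genome, then filters and applies the
#' indels; rounds repeat until one applies nothing (or `max_rounds`).  A
#' repeated genome state (oscillation) aborts with a diagnostic.
#'
#' @param genome Named character vector.
#' @param caller A pure function `genome -> variant table`.
#' @param min_support Minimum support fraction for integration.
#' @param max_rounds Round cap.
#' @return List with `genome` (polished) and `rounds`, a data.frame with
#'   one row per round: `round`, `n_snps_applied`, `n_indels_applied`,
#'   `n_rejected_support`.
#' @export
polish_iterate <- function(genome, caller, min_support = 0.6,
                           max_rounds = 10L) {
  seen <- list(genome)
  rounds <- list()
  for (r in seq_len(max_rounds)) {
    snp <- apply_variants(genome, caller(genome), min_support, "SNP")
    genome <- snp$genome
    ind <- apply_variants(genome, caller(genome), min_support,
                          c("INS", "DEL"))
    genome <- ind$genome
    n_rej <- sum(snp$rejected$reason == "support") +
      sum(ind$rejected$reason == "support")
    rounds[[r]] <- data.frame(round = r,
                              n_snps_applied = nrow(snp$applied),
                              n_indels_applied = nrow(ind$applied),
                              n_rejected_support = n_rej)
    if (nrow(snp$applied) + nrow(ind$applied) == 0L) break
    if (any(vapply(seen, identical, logical(1), y = genome)))
      stop("polishing oscillates: genome state repeated at round ", r)
    seen[[length(seen) + 1L]] <- genome
    if (r == max_rounds) break
  }
  list(genome = genome, rounds = do.call(rbind, rounds))
}
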