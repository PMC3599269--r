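#' Build synteny blocks from syntenic ortholog assignments
#'
#' Greedy left-to-right scan of the query gene order: the current block is
#' extended while the next assigned pair continues on the same target
#' chromosome with target index step +1 (orientation `same`) or -1
#' (`inverted`); otherwise the block is closed.  Blocks with fewer than
#' `min_block_genes` pairs are discarded (counted in attribute
#' `n_discarded`).
#'
#' @param assignments Assignment table; only syntenic classes are used.
#' @param query_order,target_order [gene_order()] objects.
#' @param min_block_genes Minimum pairs per block.
#' @return Data.frame, one row per block: chromosomes, query/target index
#'   ranges, orientation, `n_genes`, and the first/last gene ids on both
#'   sides.
#' @export
build_blocks <- function(assignments, query_order, target_order,
                         min_block_genes = 2L) {
  syn <- assignments[assignments$class %in%
                       c("syntenic_first_pass", "syntenic_rescued"), ,
                     drop = FALSE]
  partner <- setNames(syn$target_id, syn$query_id)
  ti <- setNames(target_order$index$idx, target_order$index$gene_id)
  tc <- setNames(target_order$index$chrom, target_order$index$gene_id)
  blocks <- list()
  open <- NULL
  close_block <- function() {
    if (!is.null(open)) blocks[[length(blocks) + 1L]] <<- open
    open <<- NULL
  }
  for (chrom in names(query_order$by_chrom)) {
    close_block()
    ids <- query_order$by_chrom[[chrom]]
    for (i in seq_along(ids)) {
      qid <- ids[i]
      tid <- partner[qid]
      if (is.na(tid)) next
      pair <- list(q_idx = i - 1L, t_idx = unname(ti[[tid]]),
                   q_gene = qid, t_gene = unname(tid),
                   t_chrom = unname(tc[[tid]]))
      if (is.null(open)) {
        open <- data.frame(
          query_chrom = chrom, target_chrom = pair$t_chrom,
          q_first_idx = pair$q_idx, q_last_idx = pair$q_idx,
          t_first_idx = pair$t_idx, t_last_idx = pair$t_idx,
          orientation = NA_character_, n_genes = 1L,
          q_first_gene = qid, q_last_gene = qid,
          t_first_gene = pair$t_gene, t_last_gene = pair$t_gene,
          stringsAsFactors = FALSE)
        next
      }
      step <- pair$t_idx - open$t_last_idx
      dir_ok <- pair$t_chrom == open$target_chrom &&
        ((is.na(open$orientation) && abs(step) == 1L) ||
         (identical(open$orientation, "same") && step == 1L) ||
         (identical(open$orientation, "inverted") && step == -1L))
      if (dir_ok) {
        if (is.na(open$orientation))
          open$orientation <- if (step == 1L) "same" else "inverted"
        open$q_last_idx <- pair$q_idx
        open$t_last_idx <- pair$t_idx
        open$q_last_gene <- qid
        open$t_last_gene <- pair$t_gene
        open$n_genes <- open$n_genes + 1L
      } else {
        close_block()
        open <- data.frame(
          query_chrom = chrom, target_chrom = pair$t_chrom,
          q_first_idx = pair$q_idx, q_last_idx = pair$q_idx,
          t_first_idx = pair$t_idx, t_last_idx = pair$t_idx,
          orientation = NA_character_, n_genes = 1L,
          q_first_gene = qid, q_last_gene = qid,
          t_first_gene = pair$t_gene, t_last_gene = pair$t_gene,
          stringsAsFactors = FALSE)
      }
    }
  }
  close_block()
  if (!length(blocks))
    return(structure(data.frame(), n_discarded = 0L))
  bl <- do.call(rbind, blocks)
  bl$orientation[is.na(bl$orientation)] <- "same"  # singletons
  short <- bl$n_genes < min_block_genes
  out <- bl[!short, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(short)
  out
}

interval_between <- function(genes, id_a, id_b) {
  ga <- genes[genes$gene_id == id_a, ]
  gb <- genes[genes$gene_id == id_b, ]
  left <- if (ga$start <= gb$start) ga else gb
  right <- if (ga$start <= gb$start) gb else ga
  data.frame(chrom = left$chrom, start = left$end, end = right$start,
             left_gene = left$gene_id, right_gene = right$gene_id,
             stringsAsFactors = FALSE)
}

# collapse consecutive blocks sharing a target chromosome into segments
collapse_segments <- function(bl_q) {
  segs <- list()
  for (i in seq_len(nrow(bl_q))) {
    if (length(segs) &&
        segs[[length(segs)]]$target_chrom == bl_q$target_chrom[i]) {
      segs[[length(segs)]]$last <- i
    } else {
      segs[[length(segs) + 1L]] <- list(
        target_chrom = bl_q$target_chrom[i], first = i, last = i)
    }
  }
  segs
}

#' Detect reciprocal translocations from synteny blocks
#'
#' A reciprocal translocation is a pair of query chromosomes whose
#' collapsed target-chromosome sequences are `(A, B)` and `(B, A)`: each
#' maps to a prefix of one target chromosome followed by a suffix of the
#' other.  Breakpoints are reported as the intergenic interval at the
#' segment junction in both genomes.  Query chromosomes with three or
#' more target segments that cannot be paired are reported as
#' `complex` events rather than forced into pairs.
#'
#' @param blocks Output of [build_blocks()].
#' @param query_genes,target_genes [make_genes()] tables (for breakpoint
#'   coordinates).
#' @return List of events; each has `type`, the chromosomes involved and
#'   a `breakpoints` data.frame (`genome`, `chrom`, `start`, `end`,
#'   `left_gene`, `right_gene`).
#' @export
detect_translocations <- function(blocks, query_genes, target_genes) {
  if (!nrow(blocks)) return(list())
  events <- list()
  segs_of <- list()
  for (qc in unique(blocks$query_chrom)) {
    bl_q <- blocks[blocks$query_chrom == qc, , drop = FALSE]
    segs_of[[qc]] <- list(blocks = bl_q, segs = collapse_segments(bl_q))
  }
  two_seg <- names(segs_of)[vapply(segs_of, function(x)
    length(x$segs) == 2L, logical(1))]
  used <- character(0)
  for (q1 in two_seg) {
    if (q1 %in% used) next
    s1 <- segs_of[[q1]]$segs
    a <- s1[[1L]]$target_chrom; b <- s1[[2L]]$target_chrom
    if (a == b) next
    for (q2 in setdiff(two_seg, c(q1, used))) {
      s2 <- segs_of[[q2]]$segs
      if (!(s2[[1L]]$target_chrom == b && s2[[2L]]$target_chrom == a)) next
      b1 <- segs_of[[q1]]$blocks; b2 <- segs_of[[q2]]$blocks
      bp <- rbind(
        cbind(genome = "query",
              interval_between(query_genes,
                               b1$q_last_gene[s1[[1L]]$last],
                               b1$q_first_gene[s1[[2L]]$first])),
        cbind(genome = "query",
              interval_between(query_genes,
                               b2$q_last_gene[s2[[1L]]$last],
                               b2$q_first_gene[s2[[2L]]$first])),
        # target chromosome A: junction between q1's prefix and q2's suffix
        cbind(genome = "target",
              interval_between(target_genes,
                               b1$t_last_gene[s1[[1L]]$last],
                               b2$t_first_gene[s2[[2L]]$first])),
        cbind(genome = "target",
              interval_between(target_genes,
                               b2$t_last_gene[s2[[1L]]$last],
                               b1$t_first_gene[s1[[2L]]$first])))
      events[[length(events) + 1L]] <- list(
        type = "reciprocal_translocation",
        query_chroms = c(q1, q2), target_chroms = c(a, b),
        breakpoints = bp)
      used <- c(used, q1, q2)
      break
    }
  }
  multi <- names(segs_of)[vapply(segs_of, function(x)
    length(x$segs) > 2L, logical(1))]
  unpaired <- setdiff(two_seg, used)
  for (qc in c(multi, unpaired)) {
    segs <- segs_of[[qc]]$segs
    if (length(unique(vapply(segs, `[[`, "", "target_chrom"))) < 2L) next
    events[[length(events) + 1L]] <- list(
      type = "complex", query_chroms = qc,
      target_chroms = unique(vapply(segs, `[[`, "", "target_chrom")),
      breakpoints = NULL)
  }
  events
}

#' Detect inversions from synteny blocks
#'
#' Each inverted-orientation block emits one event.  Breakpoints are the
#' intergenic intervals to the flanking blocks on the same chromosome
#' pair; when no flanking block exists (a whole-chromosome inversion) the
#' corresponding breakpoint runs to the chromosome end (`NA` coordinate
#' bound).
#'
#' @inheritParams detect_translocations
#' @return List of events (see [detect_translocations()]).
#' @export
detect_inversions <- function(blocks, query_genes, target_genes) {
  if (!nrow(blocks)) return(list())
  events <- list()
  for (qc in unique(blocks$query_chrom)) {
    bl_q <- blocks[blocks$query_chrom == qc, , drop = FALSE]
    inv <- which(bl_q$orientation == "inverted")
    for (i in inv) {
      side <- function(nb, this_first_q, this_first_t, edge) {
        if (nb >= 1L && nb <= nrow(bl_q) &&
            bl_q$target_chrom[nb] == bl_q$target_chrom[i]) {
          nb_gene_q <- if (edge == "left") bl_q$q_last_gene[nb] else
            bl_q$q_first_gene[nb]
          nb_gene_t <- if (edge == "left") bl_q$t_last_gene[nb] else
            bl_q$t_first_gene[nb]
          rbind(cbind(genome = "query",
                      interval_between(query_genes, nb_gene_q, this_first_q)),
                cbind(genome = "target",
                      interval_between(target_genes, nb_gene_t, this_first_t)))
        } else {
          g <- query_genes[query_genes$gene_id == this_first_q, ]
          t <- target_genes[target_genes$gene_id == this_first_t, ]
          rbind(data.frame(genome = "query", chrom = g$chrom,
                           start = if (edge == "left") NA_real_ else g$end,
                           end = if (edge == "left") g$start else NA_real_,
                           left_gene = NA_character_,
                           right_gene = g$gene_id, stringsAsFactors = FALSE),
                data.frame(genome = "target", chrom = t$chrom,
                           start = if (edge == "left") NA_real_ else t$end,
                           end = if (edge == "left") t$start else NA_real_,
                           left_gene = NA_character_,
                           right_gene = t$gene_id, stringsAsFactors = FALSE))
        }
      }
      bp <- rbind(side(i - 1L, bl_q$q_first_gene[i], bl_q$t_first_gene[i],
                       "left"),
                  side(i + 1L, bl_q$q_last_gene[i], bl_q$t_last_gene[i],
                       "right"))
      events[[length(events) + 1L]] <- list(
        type = "inversion", query_chroms = qc,
        target_chroms = bl_q$target_chrom[i], breakpoints = bp)
    }
  }
  events
}

#' List annotated features near rearrangement breakpoints
#'
#' @param event One event from [detect_translocations()] or
#'   [detect_inversions()].
#' @param features Data.frame with columns `chrom`, `start`, `end` and an
#'   id column (first non-coordinate column is used), e.g. a tRNA table;
#'   distances are strand-independent.
#' @param max_dist Maximum gap (bp) between feature and breakpoint
#'   interval.
#' @param genome_side Which genome's breakpoints to annotate.
#' @return The event with an added `nearby` data.frame (`feature_id`,
#'   `chrom`, `distance`).
#' @export
annotate_breakpoint_features <- function(event, features, max_dist = 1000,
                                         genome_side = "target") {
  bp <- event$breakpoints
  id_col <- setdiff(names(features), c("chrom", "start", "end", "strand"))[1L]
  rows <- list()
  if (!is.null(bp)) {
    bp <- bp[bp$genome == genome_side, , drop = FALSE]
    for (i in seq_len(nrow(bp))) {
      lo <- if (is.na(bp$start[i])) -Inf else bp$start[i]
      hi <- if (is.na(bp$end[i])) Inf else bp$end[i]
      f <- features[features$chrom == bp$chrom[i], , drop = FALSE]
      if (!nrow(f)) next
      d <- pmax(0, pmax(lo - f$end, f$start - hi))
      sel <- which(d <= max_dist)
      if (length(sel))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = f[[id_col]][sel], chrom = f$chrom[sel],
          distance = d[sel], stringsAsFactors = FALSE)
    }
  }
  event$nearby <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(feature_id = character(), chrom = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  event
}
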