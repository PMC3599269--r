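#' Gene order index
#'
#' Per-chromosome ordered gene lists with a dense 0-based position index,
#' the coordinate system for all synteny reasoning.
#'
#' @param genes A [make_genes()] table.
#' @return A list of class `gene_order` with `by_chrom` (named list of
#'   gene-id vectors ordered by start) and `index` (data.frame `gene_id`,
#'   `chrom`, `idx`).
#' @export
gene_order <- function(genes) {
  g <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  by_chrom <- split(g$gene_id, g$chrom)
  idx <- data.frame(
    gene_id = unlist(by_chrom, use.names = FALSE),
    chrom = rep(names(by_chrom), lengths(by_chrom)),
    idx = unlist(lapply(by_chrom, function(x) seq_along(x) - 1L),
                 use.names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(by_chrom = by_chrom, index = idx), class = "gene_order")
}

order_lookup <- function(ord, gene_ids) {
  m <- match(gene_ids, ord$index$gene_id)
  data.frame(gene_id = gene_ids, chrom = ord$index$chrom[m],
             idx = ord$index$idx[m], stringsAsFactors = FALSE)
}

#' Resolve ranked hits to target genes by maximal exonic overlap
#'
#' Each hit is assigned to the target gene whose exonic span overlaps the
#' hit interval by the largest base count (ties broken by gene id); hits
#' overlapping no gene resolve to `NA`.  Resolution is independent of hit
#' list order.
#'
#' @param hits Ranked hit table (see [rank_hits()]).
#' @param target_genes [make_genes()] table of the target genome.
#' @return Data.frame `query_id`, `rank`, `gene_id` sorted by
#'   `(query_id, rank)`.
#' @export
map_top_hits_to_genes <- function(hits, target_genes) {
  hits <- hits[order(hits$query_id, hits$rank), , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(), rank = integer(),
                      gene_id = character(), stringsAsFactors = FALSE))
  ex <- do.call(rbind, lapply(seq_len(nrow(target_genes)), function(i) {
    m <- target_genes$exons[[i]]
    data.frame(gene = i, chrom = target_genes$chrom[i],
               start = m[, 1L], end = m[, 2L], stringsAsFactors = FALSE)
  }))
  hr <- IRanges::IRanges(start = hits$start + 1L, end = hits$end)
  er <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  ov <- IRanges::findOverlaps(hr, er)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  same_chrom <- hits$chrom[qh] == ex$chrom[sh]
  qh <- qh[same_chrom]; sh <- sh[same_chrom]
  olap <- IRanges::width(IRanges::pintersect(hr[qh], er[sh]))
  resolved <- rep(NA_character_, nrow(hits))
  if (length(qh)) {
    d <- data.frame(hit = qh, gene = ex$gene[sh], olap = olap)
    # sum overlap over exons of one gene, then take the max-overlap gene
    agg <- stats::aggregate(olap ~ hit + gene, data = d, FUN = sum)
    agg$gene_id <- target_genes$gene_id[agg$gene]
    agg <- agg[order(agg$hit, -agg$olap, agg$gene_id), , drop = FALSE]
    best <- agg[!duplicated(agg$hit), , drop = FALSE]
    resolved[best$hit] <- best$gene_id
  }
  data.frame(query_id = hits$query_id, rank = hits$rank,
             gene_id = resolved, stringsAsFactors = FALSE)
}

new_assignments <- function(query_ids) {
  data.frame(query_id = query_ids, target_id = NA_character_,
             class = "unassigned", round = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Rank-1 target gene per query
#'
#' @param hit_genes Resolved hit table from [map_top_hits_to_genes()].
#' @return Named character vector, query id -> top-hit target gene id
#'   (queries whose best hit resolves to no gene are absent).
#' @export
top_hit_map <- function(hit_genes) {
  r1 <- hit_genes[hit_genes$rank == 1L & !is.na(hit_genes$gene_id), ,
                  drop = FALSE]
  setNames(r1$gene_id, r1$query_id)
}

#' First-pass syntenic ortholog assignment by conserved triplets
#'
#' For every run of three consecutive query genes on one chromosome whose
#' top-hit genes are all defined, lie on one target chromosome and occupy
#' consecutive target indices in either ascending or descending order,
#' the middle gene is assigned its top-hit gene with class
#' `syntenic_first_pass`.  A target gene claimed by two different middle
#' genes voids both claims.
#'
#' @param query_order,target_order [gene_order()] objects.
#' @param top_hit_gene Named character vector, query gene id -> top-hit
#'   target gene id (see [top_hit_map()]).
#' @return Assignment table `query_id`, `target_id`, `class`, `round`
#'   covering every query gene.
#' @export
assign_first_pass <- function(query_order, top_hit_gene, target_order) {
  asn <- new_assignments(query_order$index$gene_id)
  tl <- order_lookup(target_order, unname(top_hit_gene))
  t_chrom <- setNames(tl$chrom, names(top_hit_gene))
  t_idx <- setNames(tl$idx, names(top_hit_gene))
  claims <- list()
  for (chrom in names(query_order$by_chrom)) {
    ids <- query_order$by_chrom[[chrom]]
    if (length(ids) < 3L) next
    for (i in 2:(length(ids) - 1L)) {
      trip <- ids[(i - 1L):(i + 1L)]
      tg <- top_hit_gene[trip]
      if (any(is.na(tg)) || length(tg) < 3L) next
      ch <- t_chrom[trip]; ix <- t_idx[trip]
      if (any(is.na(ch)) || length(unique(ch)) != 1L) next
      st <- diff(ix)
      if (!(all(st == 1L) || all(st == -1L))) next
      claims[[length(claims) + 1L]] <-
        data.frame(query_id = ids[i], target_id = unname(tg[2L]),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(claims)) {
    cl <- do.call(rbind, claims)
    # a target claimed by two different middle genes voids both claims
    n_claim <- table(cl$target_id)
    multi <- names(n_claim)[n_claim > 1L]
    cl <- cl[!(cl$target_id %in% multi), , drop = FALSE]
    m <- match(cl$query_id, asn$query_id)
    asn$target_id[m] <- cl$target_id
    asn$class[m] <- "syntenic_first_pass"
    asn$round[m] <- 0L
  }
  asn
}

#' Iterative rescue of syntenic orthologs from lower-ranked hits
#'
#' For each unassigned query gene, the nearest syntenically assigned query
#' genes to its left and right on the same chromosome anchor an open
#' target-index window (their partners must share a target chromosome;
#' either orientation).  Among the query's ranked hit genes (up to
#' `max_rank`), those strictly inside the window and not yet claimed are
#' candidates; exactly one candidate assigns the gene with class
#' `syntenic_rescued`.  Genes lying beyond the outermost anchor of their
#' chromosome (terminal runs) use a one-sided window bounded by the
#' chromosome terminus, oriented by the two nearest anchors on the
#' populated side.  Rounds repeat until a full pass adds nothing, so the
#' assignment set grows monotonically and newly assigned genes tighten
#' later windows.
#'
#' @param assignments Assignment table from [assign_first_pass()].
#' @param hit_genes Resolved hit table from [map_top_hits_to_genes()].
#' @param query_order,target_order [gene_order()] objects.
#' @param max_rank Deepest hit rank considered.
#' @param max_rounds Safety cap on rounds.
#' @return Updated assignment table; attribute `rounds` records the
#'   number of productive rounds.
#' @export
rescue_iterative <- function(assignments, hit_genes, query_order,
                             target_order, max_rank = 10L,
                             max_rounds = 50L) {
  asn <- assignments
  hg <- hit_genes[!is.na(hit_genes$gene_id) & hit_genes$rank <= max_rank, ,
                  drop = FALSE]
  cand_of <- split(hg$gene_id, hg$query_id)
  ti <- setNames(target_order$index$idx, target_order$index$gene_id)
  tc <- setNames(target_order$index$chrom, target_order$index$gene_id)
  syn_classes <- c("syntenic_first_pass", "syntenic_rescued")
  rounds <- 0L
  repeat {
    if (rounds >= max_rounds) break
    added <- 0L
    claimed <- asn$target_id[!is.na(asn$target_id)]
    assigned_syn <- setNames(asn$class %in% syn_classes, asn$query_id)
    cls <- setNames(asn$class, asn$query_id)
    partner <- setNames(asn$target_id, asn$query_id)
    new_rows <- list()
    for (chrom in names(query_order$by_chrom)) {
      ids <- query_order$by_chrom[[chrom]]
      syn_here <- which(assigned_syn[ids])
      if (!length(syn_here)) next
      # bounded window centred on the nearest anchor of one side; the
      # reach extrapolates the query-side distance (plus slack), and the
      # already-claimed filter plus the single-candidate rule keep wrong
      # rescues out.  Direction is not inferred: an anchor inside an
      # inverted block would point it the wrong way.
      one_sided <- function(anchors, q_dist, slack = 5L) {
        if (!length(anchors)) return(NULL)
        a1 <- partner[[ids[anchors[1L]]]]
        reach <- q_dist + slack
        list(chrom = tc[[a1]], lo = ti[[a1]] - reach - 1L,
             hi = ti[[a1]] + reach + 1L)
      }
      for (i in which(cls[ids] == "unassigned")) {
        qid <- ids[i]
        left <- sort(syn_here[syn_here < i], decreasing = TRUE)
        right <- sort(syn_here[syn_here > i])
        windows <- list()
        if (length(left) && length(right) &&
            tc[[partner[[ids[left[1L]]]]]] ==
            tc[[partner[[ids[right[1L]]]]]]) {
          lp <- partner[[ids[left[1L]]]]
          rp <- partner[[ids[right[1L]]]]
          win <- sort(c(ti[[lp]], ti[[rp]]))
          windows <- list(list(chrom = tc[[lp]], lo = win[1L],
                               hi = win[2L]))
        } else {
          # chromosome terminus or synteny discontinuity (anchors on
          # different target chromosomes): one-sided windows per side
          windows <- Filter(Negate(is.null), list(
            if (length(left)) one_sided(left, i - left[1L]),
            if (length(right)) one_sided(right, right[1L] - i)))
        }
        if (!length(windows)) next
        cands <- unique(cand_of[[qid]])
        if (is.null(cands)) next
        ok <- Reduce(`|`, lapply(windows, function(w)
          !is.na(ti[cands]) & tc[cands] == w$chrom &
            ti[cands] > w$lo & ti[cands] < w$hi))
        cands <- cands[ok & !(cands %in% claimed)]
        if (length(cands) == 1L)
          new_rows[[length(new_rows) + 1L]] <-
            c(query_id = qid, target_id = cands)
      }
    }
    if (length(new_rows)) {
      nr <- do.call(rbind, new_rows)
      # a target proposed for two queries in one round stays unassigned
      dup <- nr[, "target_id"] %in% nr[duplicated(nr[, "target_id"]),
                                       "target_id"]
      nr <- nr[!dup, , drop = FALSE]
      if (nrow(nr)) {
        m <- match(nr[, "query_id"], asn$query_id)
        asn$target_id[m] <- nr[, "target_id"]
        asn$class[m] <- "syntenic_rescued"
        asn$round[m] <- rounds + 1L
        added <- nrow(nr)
      }
    }
    if (added == 0L) break
    rounds <- rounds + 1L
  }
  attr(asn, "rounds") <- rounds
  asn
}

#' Non-syntenic fallback assignment
#'
#' Remaining unassigned queries (iterated in gene-id order for
#' determinism) take their rank-1 target gene with class `non_syntenic`
#' unless that target is already claimed or its interval overlaps a
#' target gene assigned to a different query.
#'
#' @param assignments Assignment table after rescue.
#' @param top_hit_gene Named vector, query id -> rank-1 target gene id.
#' @param target_genes [make_genes()] table (for overlap checks).
#' @return Updated assignment table.
#' @export
assign_non_syntenic <- function(assignments, top_hit_gene, target_genes) {
  asn <- assignments
  todo <- sort(asn$query_id[asn$class == "unassigned"])
  spans <- IRanges::IRanges(start = target_genes$start + 1L,
                            end = target_genes$end)
  for (qid in todo) {
    tid <- top_hit_gene[qid]
    if (is.na(tid) || is.null(tid) || length(tid) == 0L) next
    tid <- unname(tid)
    claimed <- asn$target_id[!is.na(asn$target_id)]
    if (tid %in% claimed) next
    ti <- match(tid, target_genes$gene_id)
    if (is.na(ti)) next
    same <- which(target_genes$chrom == target_genes$chrom[ti])
    ov <- same[IRanges::overlapsAny(spans[same], spans[ti])]
    ov_ids <- setdiff(target_genes$gene_id[ov], tid)
    if (any(ov_ids %in% claimed)) next
    m <- match(qid, asn$query_id)
    asn$target_id[m] <- tid
    asn$class[m] <- "non_syntenic"
  }
  asn
}

#' Run the full three-stage ortholog assignment
#'
#' First pass ([assign_first_pass()]), iterative rescue
#' ([rescue_iterative()]) and non-syntenic fallback
#' ([assign_non_syntenic()]).
#'
#' @param query_genes,target_genes [make_genes()] tables.
#' @param hits Ranked hit table.
#' @param config A [pipeline_config()].
#' @return Assignment table covering every query gene.
#' @export
run_ortholog_pipeline <- function(query_genes, target_genes, hits,
                                  config = pipeline_config()) {
  qo <- gene_order(query_genes)
  to <- gene_order(target_genes)
  hg <- map_top_hits_to_genes(hits, target_genes)
  top1 <- top_hit_map(hg)
  asn <- assign_first_pass(qo, top1, to)
  asn <- rescue_iterative(asn, hg, qo, to, max_rank = config$rescue_max_rank)
  asn <- assign_non_syntenic(asn, top1, target_genes)
  check_assignments(asn)
  asn
}

check_assignments <- function(asn) {
  syn <- asn$class %in% c("syntenic_first_pass", "syntenic_rescued",
                          "non_syntenic")
  if (any(syn & is.na(asn$target_id)))
    stop("assigned class without a target gene")
  tg <- asn$target_id[!is.na(asn$target_id)]
  if (anyDuplicated(tg))
    stop("target gene claimed twice: ",
         paste(unique(tg[duplicated(tg)]), collapse = ", "))
  invisible(asn)
}
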