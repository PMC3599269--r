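# ---- unit-list machinery -----------------------------------------------
# A chromosome is held as an ordered list of units:
#   kind "inter" : intergenic sequence, may carry tRNAs (local coords)
#   kind "gene"  : one single-exon ORF
#   kind "bp"    : zero-length marker recording a rearrangement junction
# Each sequence unit remembers its ancestral location (anc_chrom, anc_start)
# so that planted breakpoints can be reported in both genomes' coordinates.

unit_inter <- function(seq, anc_chrom, anc_start, trnas = NULL) {
  list(kind = "inter", seq = seq, anc_chrom = anc_chrom,
       anc_start = anc_start, trnas = trnas)
}
unit_gene <- function(seq, anc_chrom, anc_start, gene_id, strand) {
  list(kind = "gene", seq = seq, anc_chrom = anc_chrom,
       anc_start = anc_start, gene_id = gene_id, strand = strand)
}
unit_bp <- function(label, anc_chrom, anc_pos) {
  list(kind = "bp", seq = "", anc_chrom = anc_chrom, anc_start = anc_pos,
       label = label)
}

parse_units <- function(genome, genes, trnas) {
  units <- list()
  for (chrom in names(genome)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    tr <- trnas[trnas$chrom == chrom, , drop = FALSE]
    ul <- list(); prev <- 0L
    slice_inter <- function(s, e) {
      keep <- tr[tr$start >= s & tr$end <= e, , drop = FALSE]
      if (nrow(keep)) {
        keep$start <- keep$start - s; keep$end <- keep$end - s
      } else keep <- NULL
      unit_inter(substr(genome[[chrom]], s + 1L, e), chrom, s, keep)
    }
    for (i in seq_len(nrow(g))) {
      ul[[length(ul) + 1L]] <- slice_inter(prev, g$start[i])
      ul[[length(ul) + 1L]] <- unit_gene(
        substr(genome[[chrom]], g$start[i] + 1L, g$end[i]),
        chrom, g$start[i], g$gene_id[i], g$strand[i])
      prev <- g$end[i]
    }
    ul[[length(ul) + 1L]] <- slice_inter(prev, nchar(genome[[chrom]]))
    units[[chrom]] <- ul
  }
  units
}

revcomp_unit <- function(u) {
  len <- nchar(u$seq)
  u$seq <- if (len) revcomp(u$seq) else u$seq
  if (u$kind == "gene") u$strand <- if (u$strand == "+") "-" else "+"
  if (u$kind == "inter" && !is.null(u$trnas)) {
    tr <- u$trnas
    new_start <- len - tr$end
    tr$end <- len - tr$start
    tr$start <- new_start
    tr$strand <- ifelse(tr$strand == "+", "-", "+")
    u$trnas <- tr
  }
  u
}

# split an inter unit at local offset `off`, avoiding tRNA spans
split_inter <- function(u, off) {
  tr <- u$trnas
  left_tr <- right_tr <- NULL
  if (!is.null(tr) && nrow(tr)) {
    if (any(tr$start < off & tr$end > off)) return(NULL)  # would cut a tRNA
    left_tr <- tr[tr$end <= off, , drop = FALSE]
    right_tr <- tr[tr$start >= off, , drop = FALSE]
    if (nrow(right_tr)) {
      right_tr$start <- right_tr$start - off
      right_tr$end <- right_tr$end - off
    }
    if (!nrow(left_tr)) left_tr <- NULL
    if (!nrow(right_tr)) right_tr <- NULL
  }
  list(unit_inter(substr(u$seq, 1L, off), u$anc_chrom, u$anc_start, left_tr),
       unit_inter(substr(u$seq, off + 1L, nchar(u$seq)), u$anc_chrom,
                  u$anc_start + off, right_tr))
}

gene_positions <- function(ul) which(vapply(ul, `[[`, "", "kind") == "gene")

# pick a split point inside the inter unit immediately before/after a gene
# unit; returns list(idx, off) or NULL if infeasible
pick_split <- function(ul, gene_idx, side) {
  idx <- if (side == "before") gene_idx - 1L else gene_idx + 1L
  if (idx < 1L || idx > length(ul)) return(NULL)
  u <- ul[[idx]]
  if (u$kind != "inter" || nchar(u$seq) < 4L) return(NULL)
  for (try in 1:20) {
    off <- sample.int(nchar(u$seq) - 2L, 1L)
    sp <- split_inter(u, off)
    if (!is.null(sp)) return(list(idx = idx, off = off, parts = sp))
  }
  NULL
}

apply_inversion <- function(ul, i_gene, j_gene, label) {
  left <- pick_split(ul, i_gene, "before")
  right <- pick_split(ul, j_gene, "after")
  if (is.null(left) || is.null(right)) return(NULL)
  lu <- ul[[left$idx]]; ru <- ul[[right$idx]]
  mid <- c(left$parts[2L],
           ul[(left$idx + 1L):(right$idx - 1L)],
           right$parts[1L])
  mid <- lapply(rev(mid), revcomp_unit)
  c(ul[seq_len(left$idx - 1L)],
    left$parts[1L],
    list(unit_bp(paste0(label, "_L"), lu$anc_chrom, lu$anc_start + left$off)),
    mid,
    list(unit_bp(paste0(label, "_R"), ru$anc_chrom, ru$anc_start + right$off)),
    right$parts[2L],
    ul[seq(right$idx + 1L, length.out = length(ul) - right$idx)])
}

# ---- evolve -------------------------------------------------------------

#' Evolve a descendant genome from an ancestor with known ground truth
#'
#' Applies, in order: gene loss, inversions (>= 2 genes, intergenic
#' breakpoints), reciprocal translocations (suffix swaps between
#' chromosome pairs at intergenic breakpoints), substitutions (never
#' creating in-frame stops or touching start/stop codons of retained
#' genes), and +-1 bp indels planted in homopolymer runs of length
#' `>= min_run` with probability `hp_indel_rate` (times `a_bias` for A/T
#' runs).  Every event is recorded in a truth table.
#'
#' @param genome Named character vector (ancestor).
#' @param annotations List with `genes` and `trnas` tables (ancestor).
#' @param params An [evolution_params()] object.
#' @param id_prefix Prefix applied to descendant gene/tRNA/chromosome ids.
#' @return A list with `genome`, `genes`, `trnas` (the descendant) and
#'   `truth`: `pairs` (named vector, ancestor gene id -> descendant gene
#'   id), `lost` (ancestor ids), `rearrangements` (list with type, chroms
#'   and per-breakpoint ancestor/descendant coordinates) and `hp_indels`
#'   (data.frame of planted indels in descendant coordinates).
#' @export
evolve <- function(genome, annotations, params, id_prefix = "t_") {
  stopifnot(inherits(params, "evolution_params"))
  genes <- annotations$genes; trnas <- annotations$trnas
  set.seed(params$rng_seed)
  n_chrom <- length(genome)
  if (params$n_translocations > n_chrom %/% 2L)
    stop("n_translocations must be <= floor(n_chrom / 2)")
  units <- parse_units(genome, genes, trnas)
  lost <- character(0)
  rearr <- list()

  # gene loss: drop the unit, neighbouring spacers stay in place
  if (params$gene_loss_prob > 0) {
    for (chrom in names(units)) {
      ul <- units[[chrom]]
      gp <- gene_positions(ul)
      drop <- gp[runif(length(gp)) < params$gene_loss_prob]
      # never drop below 3 genes per chromosome
      if (length(gp) - length(drop) < 3L)
        drop <- head(drop, max(0L, length(gp) - 3L))
      if (length(drop)) {
        lost <- c(lost, vapply(ul[drop], `[[`, "", "gene_id"))
        units[[chrom]] <- ul[-drop]
      }
    }
  }

  # inversions: disjoint >= 2 gene segments
  inverted <- character(0)
  for (k in seq_len(params$n_inversions)) {
    done <- FALSE
    for (try in 1:100) {
      chrom <- sample(names(units), 1L)
      gp <- gene_positions(units[[chrom]])
      if (length(gp) < 6L) next
      # spans of 4-8 genes leave >= 2 interior genes, the minimum
      # signature a gene-order synteny block can resolve (the flanking
      # genes of an inverted segment lose their conserved neighbourhoods)
      span <- sample(4:min(8L, length(gp) - 1L), 1L)
      i <- sample.int(length(gp) - span + 1L, 1L)
      seg <- gp[i:(i + span - 1L)]
      ids <- vapply(units[[chrom]][seg], `[[`, "", "gene_id")
      if (any(ids %in% inverted)) next
      lab <- sprintf("inv%d", k)
      new_ul <- apply_inversion(units[[chrom]], seg[1L], seg[length(seg)], lab)
      if (is.null(new_ul)) next
      units[[chrom]] <- new_ul
      inverted <- c(inverted, ids)
      rearr[[length(rearr) + 1L]] <-
        list(type = "inversion", label = lab, chrom = chrom, genes = ids)
      done <- TRUE
      break
    }
    if (!done) stop("could not place inversion ", k,
                    " after 100 attempts (breakpoint collision)")
  }

  # reciprocal translocations: swap suffixes of a chromosome pair
  free_chroms <- names(units)
  for (k in seq_len(params$n_translocations)) {
    done <- FALSE
    for (try in 1:100) {
      if (length(free_chroms) < 2L) break
      pair <- sample(free_chroms, 2L)
      ua <- units[[pair[1L]]]; ub <- units[[pair[2L]]]
      ga <- gene_positions(ua); gb <- gene_positions(ub)
      if (length(ga) < 9L || length(gb) < 9L) next
      # arm-scale swap: both products keep >= 4 genes, the smallest run
      # the triplet-plus-rescue method can re-anchor across a junction;
      # a split adjacent to an inverted gene would cut through an
      # inversion and compound the two events (breakpoint collision)
      ia <- ga[sample(5:(length(ga) - 4L), 1L)]
      ib <- gb[sample(5:(length(gb) - 4L), 1L)]
      near_inverted <- function(ul, gi) {
        gp <- gene_positions(ul)
        nb <- gp[abs(gp - gi) <= 2L | (gp < gi & gp >= gi - 3L)]
        any(vapply(ul[union(nb, gi)], `[[`, "", "gene_id") %in% inverted)
      }
      if (near_inverted(ua, ia) || near_inverted(ub, ib)) next
      sa <- pick_split(ua, ia, "before")
      sb <- pick_split(ub, ib, "before")
      if (is.null(sa) || is.null(sb)) next
      lab <- sprintf("tra%d", k)
      ma <- unit_bp(paste0(lab, "_A"), ua[[sa$idx]]$anc_chrom,
                    ua[[sa$idx]]$anc_start + sa$off)
      mb <- unit_bp(paste0(lab, "_B"), ub[[sb$idx]]$anc_chrom,
                    ub[[sb$idx]]$anc_start + sb$off)
      new_a <- c(ua[seq_len(sa$idx - 1L)], sa$parts[1L], list(ma),
                 sb$parts[2L],
                 ub[seq(sb$idx + 1L, length.out = length(ub) - sb$idx)])
      new_b <- c(ub[seq_len(sb$idx - 1L)], sb$parts[1L], list(mb),
                 sa$parts[2L],
                 ua[seq(sa$idx + 1L, length.out = length(ua) - sa$idx)])
      units[[pair[1L]]] <- new_a
      units[[pair[2L]]] <- new_b
      free_chroms <- setdiff(free_chroms, pair)
      rearr[[length(rearr) + 1L]] <-
        list(type = "reciprocal_translocation", label = lab, chroms = pair)
      done <- TRUE
      break
    }
    if (!done) stop("could not place translocation ", k,
                    " after 100 attempts (breakpoint collision)")
  }

  # substitutions
  if (params$sub_rate > 0) {
    for (chrom in names(units)) {
      units[[chrom]] <- lapply(units[[chrom]], mutate_unit,
                               rate = params$sub_rate)
    }
  }

  # homopolymer indels
  hp_rows <- list()
  if (params$hp_indel_rate > 0) {
    for (chrom in names(units)) {
      ul <- units[[chrom]]
      for (i in seq_along(ul)) {
        res <- plant_hp_indels(ul[[i]], params)
        ul[[i]] <- res$unit
        if (!is.null(res$edits)) hp_rows[[length(hp_rows) + 1L]] <-
            cbind(unit_chrom = chrom, unit_index = i, res$edits)
      }
      units[[chrom]] <- ul
    }
  }

  assemble_units(units, hp_rows, rearr, genes, lost, id_prefix, params)
}

# substitutions within one unit; gene units keep start/stop codons intact
# and never gain an in-frame stop
mutate_unit <- function(u, rate) {
  len <- nchar(u$seq)
  if (u$kind == "bp" || len == 0L) return(u)
  s <- strsplit(u$seq, "")[[1L]]
  sites <- which(runif(len) < rate)
  if (u$kind == "gene") sites <- sites[sites > 3L & sites <= len - 3L]
  if (!length(sites)) return(u)
  if (u$kind == "inter") {
    s[sites] <- vapply(s[sites],
                       function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  } else {
    for (p in sites) {
      cod_i <- (p - 1L) %/% 3L          # codon index in genomic orientation
      ci <- cod_i * 3L + 1L
      for (b in sample(setdiff(DNA_BASES, s[p]))) {
        cand <- s[ci:(ci + 2L)]
        cand[p - ci + 1L] <- b
        cod <- paste(cand, collapse = "")
        # the codon read in coding orientation must not be a stop
        coding <- if (u$strand == "+") cod else revcomp(cod)
        if (!(coding %in% STOP_CODONS)) { s[p] <- b; break }
      }
    }
  }
  u$seq <- paste(s, collapse = "")
  u
}

# +-1 bp indels in homopolymer runs >= min_run; returns edited unit plus a
# table of edits with positions local to the edited unit sequence
plant_hp_indels <- function(u, params) {
  len <- nchar(u$seq)
  if (u$kind == "bp" || len < params$min_run) return(list(unit = u))
  s <- strsplit(u$seq, "")[[1L]]
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  elig <- which(r$lengths >= params$min_run)
  if (u$kind == "inter" && !is.null(u$trnas) && nrow(u$trnas)) {
    tr <- u$trnas
    ok <- vapply(elig, function(i) {
      !any(tr$start < ends[i] & tr$end > starts[i] - 1L)
    }, logical(1))
    elig <- elig[ok]
  }
  if (!length(elig)) return(list(unit = u))
  p_run <- params$hp_indel_rate *
    ifelse(r$values[elig] %in% c("A", "T"), params$a_bias, 1)
  hit <- elig[runif(length(elig)) < pmin(1, p_run)]
  if (!length(hit)) return(list(unit = u))
  # keep planted errors separated: opposite-sign +-1 indels a few bases
  # apart cancel in any alignment and are unidentifiable by construction
  hit <- sort(hit)
  kept <- hit[1L]
  for (h in hit[-1L])
    if (starts[h] - starts[kept[length(kept)]] >= 12L) kept <- c(kept, h)
  hit <- rev(kept)
  edits <- list()
  for (i in hit) {
    delta <- sample(c(-1L, 1L), 1L)
    p <- starts[i]                       # 1-based local position of run start
    if (delta == 1L) {
      s <- append(s, r$values[i], after = p - 1L)
    } else {
      s <- s[-p]
    }
    edits[[length(edits) + 1L]] <- data.frame(
      local_pos = p - 1L, base = r$values[i], run_len = r$lengths[i],
      delta = delta,
      gene_id = if (u$kind == "gene") u$gene_id else NA_character_,
      stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edits)
  ed <- ed[order(ed$local_pos), , drop = FALSE]
  # convert local positions to the edited sequence's coordinate frame
  shift <- cumsum(c(0L, ed$delta[-nrow(ed)]))
  ed$local_pos <- ed$local_pos + shift
  u$seq <- paste(s, collapse = "")
  list(unit = u, edits = ed)
}

assemble_units <- function(units, hp_rows, rearr, anc_genes, lost,
                           id_prefix, params) {
  genome <- character(0)
  g_rows <- list(); t_rows <- list(); bp_rows <- list()
  unit_start <- list()   # derived start per (chrom, unit index)
  for (chrom in names(units)) {
    der_chrom <- paste0(id_prefix, chrom)
    pos <- 0L; parts <- character(0)
    ul <- units[[chrom]]
    starts <- integer(length(ul))
    for (i in seq_along(ul)) {
      u <- ul[[i]]
      starts[i] <- pos
      if (u$kind == "bp") {
        bp_rows[[length(bp_rows) + 1L]] <- data.frame(
          label = u$label, der_chrom = der_chrom, der_pos = pos,
          anc_chrom = u$anc_chrom, anc_pos = u$anc_start,
          stringsAsFactors = FALSE)
        next
      }
      if (u$kind == "gene") {
        g_rows[[length(g_rows) + 1L]] <- data.frame(
          gene_id = paste0(id_prefix, u$gene_id), chrom = der_chrom,
          strand = u$strand, start = pos, end = pos + nchar(u$seq),
          anc_id = u$gene_id, stringsAsFactors = FALSE)
      }
      if (u$kind == "inter" && !is.null(u$trnas) && nrow(u$trnas)) {
        tr <- u$trnas
        t_rows[[length(t_rows) + 1L]] <- data.frame(
          trna_id = paste0(id_prefix, tr$trna_id), chrom = der_chrom,
          strand = tr$strand, start = pos + tr$start, end = pos + tr$end,
          isotype = tr$isotype, stringsAsFactors = FALSE)
      }
      parts <- c(parts, u$seq); pos <- pos + nchar(u$seq)
    }
    unit_start[[chrom]] <- starts
    genome[der_chrom] <- paste(parts, collapse = "")
  }
  gdf <- do.call(rbind, g_rows)
  genes <- make_genes(gdf$gene_id, gdf$chrom, gdf$strand,
                      start = gdf$start, end = gdf$end)
  # keep descendant gene order stable by coordinate
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_table", "data.frame")
  trnas <- if (length(t_rows)) {
    tt <- do.call(rbind, t_rows); tt[order(tt$chrom, tt$start), , drop = FALSE]
  } else make_trnas(character(), character(), character(), numeric(),
                    numeric() + 1, character())
  rownames(trnas) <- NULL

  pairs <- setNames(gdf$gene_id, gdf$anc_id)
  pairs <- pairs[setdiff(anc_genes$gene_id, lost)]

  bps <- if (length(bp_rows)) do.call(rbind, bp_rows) else NULL
  rearr <- lapply(rearr, function(ev) {
    if (!is.null(bps)) {
      ev$breakpoints <- bps[startsWith(bps$label, ev$label), , drop = FALSE]
    }
    ev
  })

  hp <- NULL
  if (length(hp_rows)) {
    hp <- do.call(rbind, hp_rows)
    der_chrom <- paste0(id_prefix, hp$unit_chrom)
    off <- mapply(function(ch, i) unit_start[[ch]][i],
                  hp$unit_chrom, hp$unit_index)
    hp <- data.frame(chrom = der_chrom, pos = off + hp$local_pos,
                     base = hp$base, run_len = hp$run_len, delta = hp$delta,
                     gene_id = ifelse(is.na(hp$gene_id), NA_character_,
                                      paste0(id_prefix, hp$gene_id)),
                     stringsAsFactors = FALSE)
    hp <- hp[order(hp$chrom, hp$pos), , drop = FALSE]
    rownames(hp) <- NULL
  } else {
    hp <- data.frame(chrom = character(), pos = numeric(), base = character(),
                     run_len = integer(), delta = integer(),
                     gene_id = character(), stringsAsFactors = FALSE)
  }

  list(genome = genome, genes = genes, trnas = trnas,
       truth = list(pairs = pairs, lost = lost, rearrangements = rearr,
                    hp_indels = hp, params = params))
}
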