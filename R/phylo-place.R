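#' Candidate placements of a focal species on a fixed backbone
#'
#' Five rooted topologies over six ingroup species plus an outgroup that
#' differ only in where the focal leaf attaches along the backbone spine
#' (sister to the basal ingroup species, at each internode, or sister to
#' the third-most-derived species).  Placement 2 -- focal diverging after
#' the common ancestor with the basal species and before the next clade
#' -- is the arrangement supported for *S. arboricolus*-like data.
#'
#' @param species Character vector of the six ingroup names, most derived
#'   pair first, basal last; the focal species is `species[5]` by
#'   convention of the returned trees.
#' @param outgroup Outgroup name.
#' @param branch_length Length assigned to every edge.
#' @return Named list of five `ape::phylo` trees (`topo1` .. `topo5`)
#'   with identical leaf sets.
#' @export
candidate_placements <- function(species = c("Scer", "Spar", "Smik",
                                             "Skud", "Sarb", "Sbay"),
                                 outgroup = "Scas",
                                 branch_length = 0.1) {
  s <- species
  txt <- c(
    sprintf("(((((%s,%s),%s),%s),(%s,%s)),%s);",
            s[1], s[2], s[3], s[4], s[6], s[5], outgroup),
    sprintf("((((((%s,%s),%s),%s),%s),%s),%s);",
            s[1], s[2], s[3], s[4], s[5], s[6], outgroup),
    sprintf("(((((%s,%s),%s),(%s,%s)),%s),%s);",
            s[1], s[2], s[3], s[4], s[5], s[6], outgroup),
    sprintf("((((((%s,%s),%s),%s),%s),%s),%s);",
            s[1], s[2], s[3], s[5], s[4], s[6], outgroup),
    sprintf("(((((%s,%s),(%s,%s)),%s),%s),%s);",
            s[1], s[2], s[3], s[5], s[4], s[6], outgroup))
  trees <- lapply(txt, function(x) {
    tr <- ape::read.tree(text = x)
    tr$edge.length <- rep(branch_length, nrow(tr$edge))
    tr
  })
  names(trees) <- paste0("topo", seq_along(trees))
  trees
}

#' Sample random gene sets for concatenated placement
#'
#' Families are eligible when they contain every species in
#' `required_species`; each set samples `k` eligible families without
#' replacement, independently across sets, deterministically by seed.
#'
#' @param families Named list of alignments (named character vectors).
#' @param k Families per set.
#' @param n Number of sets.
#' @param required_species Species that must be present (default: the
#'   union over all families).
#' @param rng_seed Integer seed.
#' @return List of `n` character vectors of family ids.
#' @export
sample_gene_sets <- function(families, k, n, required_species = NULL,
                             rng_seed = 1L) {
  if (is.null(required_species))
    required_species <- Reduce(union, lapply(families, names))
  eligible <- names(families)[vapply(families, function(f)
    all(required_species %in% names(f)), logical(1))]
  if (length(eligible) < k)
    stop("only ", length(eligible), " eligible families for sets of ", k)
  set.seed(rng_seed)
  lapply(seq_len(n), function(i) sample(eligible, k))
}

#' Concatenate aligned families
#'
#' Per-species concatenation in list order; every family must contain
#' exactly the same species set.
#'
#' @param families Named list of alignments (named character vectors of
#'   equal length within each family).
#' @return One named character vector.
#' @export
concatenate_alignments <- function(families) {
  if (!length(families)) stop("no families to concatenate")
  species <- sort(names(families[[1L]]))
  for (f in families)
    if (!setequal(names(f), species))
      stop("species missing from a family: expected ",
           paste(species, collapse = ", "))
  out <- vapply(species, function(sp)
    paste(vapply(families, function(f) unname(f[[sp]]), ""), collapse = ""),
    "")
  out
}

#' Place a focal species by repeated random gene-set concatenation
#'
#' For each of `sample_count` random sets of `genes_per_sample` families,
#' the concatenated alignment is fitted to every candidate topology by
#' [optimize_branch_lengths()]; the winner is the candidate with the
#' highest log-likelihood (ties to the lowest index, recorded in
#' attribute `ties`).  Per-sample support is the fraction of
#' `n_bootstrap` column-bootstrap replicates -- per-site log-likelihoods
#' resampled with replacement at the optimised branch lengths -- in which
#' the same candidate wins.
#'
#' @param families Named list of alignments.
#' @param candidates Named list of rooted candidate topologies sharing
#'   one leaf set (see [candidate_placements()]).
#' @param model A [substitution_model()]; `NULL` fits empirical
#'   frequencies per sample.
#' @param sample_count,genes_per_sample,n_bootstrap Sampling design.
#' @param rng_seed Integer seed.
#' @param tol,max_cycles Passed to the optimiser.
#' @return List of class `placement_result`: `per_sample` (data.frame
#'   with best topology, support and per-topology log-likelihoods),
#'   `support_counts` (wins per topology, summing to `sample_count`) and
#'   `median_lengths` (per-edge medians of the winning topology's
#'   optimised lengths).
#' @export
place_species <- function(families, candidates, model = NULL,
                          sample_count = 100L, genes_per_sample = 50L,
                          n_bootstrap = 100L, rng_seed = 1L,
                          tol = 1e-4, max_cycles = 10L) {
  taxa <- candidates[[1L]]$tip.label
  for (tr in candidates)
    if (!setequal(tr$tip.label, taxa))
      stop("candidate topologies must share one leaf set")
  sets <- sample_gene_sets(families, genes_per_sample, sample_count,
                           required_species = taxa, rng_seed = rng_seed)
  set.seed(rng_seed + 1L)
  boot_seeds <- sample.int(.Machine$integer.max %/% 2L, sample_count)
  n_topo <- length(candidates)
  per_sample <- list()
  ties <- integer(0)
  win_lengths <- list()
  for (i in seq_along(sets)) {
    aln <- concatenate_alignments(families[sets[[i]]])
    mod <- if (is.null(model)) {
      type <- if (mean(unlist(strsplit(aln, "")) %in% DNA_BASES) > 0.9)
        "nt" else "aa"
      substitution_model(type, residue_frequencies(aln, type))
    } else model
    pd <- alignment_patterns(aln, mod)
    logls <- numeric(n_topo)
    site_logl <- vector("list", n_topo)
    fits <- vector("list", n_topo)
    for (j in seq_len(n_topo)) {
      fit <- optimize_branch_lengths(pd, candidates[[j]], mod, tol = tol,
                                     max_cycles = max_cycles)
      fits[[j]] <- fit
      ls <- log_likelihood(pd, fit$tree, mod, per_site = TRUE)
      logls[j] <- ls$logL
      site_logl[[j]] <- ls$site_logl
    }
    best <- which(logls == max(logls))
    if (length(best) > 1L) ties <- c(ties, i)
    best <- best[1L]
    # RELL-style column bootstrap at the optimised branch lengths
    set.seed(boot_seeds[i])
    n_sites <- pd$n_sites
    sl <- do.call(cbind, site_logl)
    wins <- 0L
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n_sites, n_sites, replace = TRUE)
      bl <- colSums(sl[idx, , drop = FALSE])
      if (which.max(bl) == best) wins <- wins + 1L
    }
    row <- data.frame(sample = i, best_topo = names(candidates)[best],
                      support = wins / n_bootstrap)
    for (j in seq_len(n_topo)) row[[paste0("logL_", names(candidates)[j])]] <-
      logls[j]
    per_sample[[i]] <- row
    win_lengths[[i]] <- fits[[best]]$lengths
  }
  per_sample <- do.call(rbind, per_sample)
  support_counts <- table(factor(per_sample$best_topo,
                                 levels = names(candidates)))
  overall <- names(which.max(support_counts))
  wl <- do.call(rbind, win_lengths[per_sample$best_topo == overall])
  structure(list(per_sample = per_sample,
                 support_counts = support_counts,
                 overall_best = overall,
                 median_lengths = apply(wl, 2L, median),
                 ties = ties),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("placement over", nrow(x$per_sample), "gene-set samples\n")
  print(x$support_counts)
  cat("overall best:", x$overall_best, "; median support",
      sprintf("%.2f", median(x$per_sample$support)), "\n")
  invisible(x)
}

#' Per-edge median branch lengths across gene families
#'
#' Each family is fitted on the fixed topology; families whose
#' optimisation fails are excluded and counted.
#'
#' @param families Named list of alignments.
#' @param topology Rooted `ape::phylo` tree.
#' @param model A [substitution_model()].
#' @param tol,max_cycles Passed to the optimiser.
#' @return List with `median_lengths` (per edge of `topology$edge`),
#'   `n_families_used` and `n_failed`.
#' @export
median_branch_lengths <- function(families, topology, model,
                                  tol = 1e-4, max_cycles = 10L) {
  lens <- list(); failed <- 0L
  for (fid in names(families)) {
    fit <- tryCatch(
      optimize_branch_lengths(families[[fid]], topology, model,
                              tol = tol, max_cycles = max_cycles),
      error = function(e) NULL)
    if (is.null(fit)) failed <- failed + 1L
    else lens[[fid]] <- fit$lengths
  }
  if (!length(lens)) stop("no family optimised successfully")
  m <- do.call(rbind, lens)
  list(median_lengths = apply(m, 2L, median),
       n_families_used = nrow(m), n_failed = failed)
}
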