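#' Simulate an alignment on a tree
#'
#' Root states are drawn from the model's stationary distribution and
#' evolved along each edge with the model's transition matrices; only
#' tip sequences are returned.
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths.
#' @param model A [substitution_model()].
#' @param n_sites Number of sites.
#' @param rng_seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named character vector of tip sequences.
#' @export
simulate_alignment <- function(tree, model, n_sites, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  s <- length(model$states)
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1L]
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- sample.int(s, n_sites, replace = TRUE,
                               prob = model$freqs)
  for (k in rev(seq_len(nrow(po$edge)))) {   # preorder
    par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
    P <- transition_matrix(model, po$edge.length[k])
    x <- states[[par]]
    y <- integer(n_sites)
    for (st in unique(x)) {
      sel <- x == st
      y[sel] <- sample.int(s, sum(sel), replace = TRUE, prob = P[st, ])
    }
    states[[chi]] <- y
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(model$states[states[[i]]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}

#' Simulate a set of gene families on one tree
#'
#' Per-family branch lengths are jittered by a lognormal rate factor to
#' emulate among-gene rate variation.
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths.
#' @param model A [substitution_model()].
#' @param n_families Number of families.
#' @param sites_per_family Alignment length per family.
#' @param rate_jitter_sd Standard deviation of the log rate factor.
#' @param rng_seed Integer seed.
#' @return Named list of alignments (`fam0001`, ...).
#' @export
simulate_families <- function(tree, model, n_families, sites_per_family,
                              rate_jitter_sd = 0.3, rng_seed = 1L) {
  set.seed(rng_seed)
  out <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    tr <- tree
    tr$edge.length <- tr$edge.length * exp(rnorm(1, 0, rate_jitter_sd))
    out[[i]] <- simulate_alignment(tr, model, sites_per_family)
  }
  names(out) <- sprintf("fam%04d", seq_len(n_families))
  out
}

#' Read / write a directory of aligned FASTA families
#'
#' @param dir Directory of `.fa`/`.fasta` files, one aligned family per
#'   file (file stem = family id).
#' @return Named list of alignments.
#' @export
read_family_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files in ", dir)
  fams <- lapply(files, function(f) {
    set <- Biostrings::readBStringSet(f)
    setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
  })
  names(fams) <- sub("\\.(fa|fasta)$", "", basename(files))
  fams
}

#' @rdname read_family_dir
#' @param families Named list of alignments.
#' @export
write_family_dir <- function(families, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fid in names(families)) {
    f <- families[[fid]]
    set <- Biostrings::BStringSet(f)
    Biostrings::writeXStringSet(set, file.path(dir, paste0(fid, ".fa")))
  }
  invisible(dir)
}
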