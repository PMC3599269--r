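#' Encode an alignment into compressed site patterns
#'
#' Characters outside the model alphabet (gaps, `X`, `?`, `N` in amino
#' acid mode) are treated as fully ambiguous.  Identical columns are
#' collapsed into patterns with multiplicities; likelihood computations
#' run over patterns and expand back to sites on demand.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param model A [substitution_model()].
#' @return A list of class `pattern_data`: `pat` (taxa x patterns state
#'   indices, 0 = ambiguous), `w` (pattern weights), `site2pat`, `taxa`,
#'   `n_sites`.
#' @export
alignment_patterns <- function(aln, model) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal lengths")
  n_sites <- lens[[1L]]
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  idx <- matrix(match(m, model$states, nomatch = 0L), nrow(m), ncol(m))
  key <- apply(idx, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  site2pat <- match(key, key[u])
  structure(list(pat = idx[, u, drop = FALSE],
                 w = as.numeric(tabulate(site2pat, sum(u))),
                 site2pat = site2pat,
                 taxa = names(aln), n_sites = n_sites),
            class = "pattern_data")
}

# tree bookkeeping shared by the pruning and optimisation code
tree_arrays <- function(tree, taxa) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips and alignment taxa differ")
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1L]
  list(edge = po$edge, ntip = ntip, root = root,
       n_nodes = ntip + tree$Nnode,
       tip_of = match(tree$tip.label, taxa))
}

# fast column maxima / column rescale for small-row matrices
col_max <- function(x) do.call(pmax, lapply(seq_len(nrow(x)),
                                            function(i) x[i, ]))
col_scale <- function(x, mx) x * rep(1 / mx, each = nrow(x))

tip_conditional <- function(pd, model, tip, taxon_row) {
  s <- length(model$states)
  states <- pd$pat[taxon_row, ]
  L <- matrix(1, s, length(states))
  known <- states > 0L
  L[, known] <- 0
  L[cbind(states[known], which(known))] <- 1
  L
}

# postorder conditional likelihoods for all nodes
down_pass <- function(ta, pd, model, lens) {
  s <- length(model$states)
  npat <- ncol(pd$pat)
  D <- vector("list", ta$n_nodes)
  sc <- vector("list", ta$n_nodes)
  for (tip in seq_len(ta$ntip)) {
    D[[tip]] <- tip_conditional(pd, model, tip, ta$tip_of[tip])
    sc[[tip]] <- numeric(npat)
  }
  for (k in seq_len(nrow(ta$edge))) {
    par <- ta$edge[k, 1L]; chi <- ta$edge[k, 2L]
    contrib <- transition_matrix(model, lens[k]) %*% D[[chi]]
    if (is.null(D[[par]])) {
      D[[par]] <- contrib
      sc[[par]] <- sc[[chi]]
    } else {
      D[[par]] <- D[[par]] * contrib
      sc[[par]] <- sc[[par]] + sc[[chi]]
    }
    mx <- col_max(D[[par]])
    mx[mx <= 0] <- 1
    D[[par]] <- col_scale(D[[par]], mx)
    sc[[par]] <- sc[[par]] + log(mx)
  }
  list(D = D, sc = sc)
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Conditional likelihoods are propagated from the tips to the root with
#' per-node rescaling; gaps and other non-alphabet characters contribute
#' a factor of one (fully ambiguous).  The model's stationary
#' distribution is the root prior, so for a reversible model the result
#' is invariant to root placement.
#'
#' @param aln Named character vector of aligned sequences, or a
#'   [alignment_patterns()] object.
#' @param tree A rooted `ape::phylo` tree with branch lengths whose tips
#'   match the alignment names.
#' @param model A [substitution_model()].
#' @param per_site Also return the per-site log-likelihood vector?
#' @return The total log-likelihood (numeric scalar); with
#'   `per_site = TRUE` a list with `logL` and `site_logl`.
#' @export
log_likelihood <- function(aln, tree, model, per_site = FALSE) {
  pd <- if (inherits(aln, "pattern_data")) aln else
    alignment_patterns(aln, model)
  ta <- tree_arrays(tree, pd$taxa)
  dp <- down_pass(ta, pd, model, ape::reorder.phylo(tree, "postorder")$edge.length)
  lr <- colSums(model$freqs * dp$D[[ta$root]])
  pat_logl <- log(lr) + dp$sc[[ta$root]]
  logL <- sum(pd$w * pat_logl)
  if (!per_site) return(logL)
  list(logL = logL, site_logl = pat_logl[pd$site2pat])
}
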