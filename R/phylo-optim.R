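# products P(t_e) %*% D[child] and outside-subtree partials per edge;
# together with down_pass() these let a single edge's length be optimised
# with one matrix product per likelihood evaluation
up_pass <- function(ta, pd, model, lens, dp) {
  s <- length(model$states)
  npat <- ncol(pd$pat)
  E <- nrow(ta$edge)
  C <- vector("list", E)
  for (k in seq_len(E))
    C[[k]] <- transition_matrix(model, lens[k]) %*% dp$D[[ta$edge[k, 2L]]]
  kids <- split(seq_len(E), ta$edge[, 1L])
  I <- vector("list", ta$n_nodes); scI <- vector("list", ta$n_nodes)
  I[[ta$root]] <- matrix(model$freqs, s, npat)
  scI[[ta$root]] <- numeric(npat)
  A <- vector("list", E); scA <- vector("list", E)
  for (k in rev(seq_len(E))) {
    u <- ta$edge[k, 1L]; v <- ta$edge[k, 2L]
    Ak <- I[[u]]; sA <- scI[[u]]
    for (j in setdiff(kids[[as.character(u)]], k)) {
      Ak <- Ak * C[[j]]
      sA <- sA + dp$sc[[ta$edge[j, 2L]]]
    }
    mx <- col_max(Ak); mx[mx <= 0] <- 1
    Ak <- col_scale(Ak, mx); sA <- sA + log(mx)
    A[[k]] <- Ak; scA[[k]] <- sA
    if (v > ta$ntip) {
      I[[v]] <- crossprod(transition_matrix(model, lens[k]), Ak)
      scI[[v]] <- sA
    }
  }
  list(A = A, scA = scA)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Cyclic coordinate-wise optimisation: each edge in turn is maximised by
#' Brent's scalar search over `[min_len, max_len]` (using cached
#' inside/outside partial likelihoods, so one evaluation costs a single
#' matrix product), and cycles repeat until the log-likelihood gain
#' drops below `tol`.  The log-likelihood never decreases.
#'
#' @param aln Named character vector of aligned sequences, or a
#'   [alignment_patterns()] object.
#' @param tree Rooted `ape::phylo` topology; its branch lengths (if any)
#'   seed the search, otherwise `init_len` is used.
#' @param model A [substitution_model()].
#' @param tol Convergence threshold in log-likelihood units.
#' @param max_cycles Cap on optimisation sweeps.
#' @param min_len,max_len Branch-length bounds.
#' @param init_len Starting length for edges lacking one.
#' @return List with `tree` (lengths filled in), `logL` and `lengths`
#'   (in the order of `tree$edge`).
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-6,
                                    max_cycles = 20L, min_len = 1e-8,
                                    max_len = 10, init_len = 0.1) {
  pd <- if (inherits(aln, "pattern_data")) aln else
    alignment_patterns(aln, model)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(init_len, nrow(tree$edge))
  ta <- tree_arrays(tree, pd$taxa)
  po <- ape::reorder.phylo(tree, "postorder")
  lens <- pmin(pmax(po$edge.length, min_len), max_len)
  logL <- -Inf
  for (cycle in seq_len(max_cycles)) {
    cycle_logL <- logL
    for (k in seq_len(nrow(ta$edge))) {
      dp <- down_pass(ta, pd, model, lens)
      upo <- up_pass(ta, pd, model, lens, dp)
      A <- upo$A[[k]]; sA <- upo$scA[[k]]
      chi <- ta$edge[k, 2L]
      Dk <- dp$D[[chi]]; sD <- dp$sc[[chi]]
      g <- function(t) {
        lv <- colSums(A * (transition_matrix(model, t) %*% Dk))
        sum(pd$w * (log(pmax(lv, 1e-300)) + sA + sD))
      }
      cur <- g(lens[k])
      opt <- optimize(g, c(min_len, max_len), maximum = TRUE, tol = 1e-7)
      if (opt$objective > cur) {
        lens[k] <- opt$maximum
        cycle_logL <- opt$objective
      } else cycle_logL <- max(cycle_logL, cur)
    }
    if (is.finite(logL) && cycle_logL - logL < tol) { logL <- cycle_logL; break }
    logL <- cycle_logL
  }
  key_po <- paste(ta$edge[, 1L], ta$edge[, 2L])
  key_tr <- paste(tree$edge[, 1L], tree$edge[, 2L])
  tree$edge.length <- lens[match(key_tr, key_po)]
  list(tree = tree, logL = logL, lengths = tree$edge.length)
}
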