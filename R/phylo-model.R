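AA_STATES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Reversible substitution model with equal exchangeabilities
#'
#' An equal-exchangeability (Poisson-type) model on amino acids or an
#' equal-rates model on nucleotides: `Q[i, j] = pi[j]` off-diagonal,
#' normalised so the expected rate at stationarity is one substitution
#' per site per unit branch length.  With uniform frequencies the
#' nucleotide model reduces to the classical equal-rates (Jukes-Cantor
#' type) model.  The eigendecomposition is cached for fast transition
#' matrices.
#'
#' @param type `"nt"` or `"aa"`.
#' @param freqs Stationary frequencies (default uniform); typically the
#'   empirical frequencies of the alignment (see [residue_frequencies()]).
#' @return A list of class `subst_model`.
#' @export
substitution_model <- function(type = c("nt", "aa"), freqs = NULL) {
  type <- match.arg(type)
  states <- if (type == "nt") DNA_BASES else AA_STATES
  s <- length(states)
  if (is.null(freqs)) freqs <- rep(1 / s, s)
  if (length(freqs) != s) stop("freqs must have length ", s)
  freqs <- freqs / sum(freqs)
  if (any(freqs <= 0)) stop("stationary frequencies must be positive")
  Q <- matrix(rep(freqs, each = s), s, s)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q <- Q / rate
  d <- sqrt(freqs)
  B <- (d * Q) %*% diag(1 / d)          # diag(d) Q diag(1/d), symmetric
  B <- (B + t(B)) / 2                   # guard against round-off asymmetry
  eig <- eigen(B, symmetric = TRUE)
  structure(list(type = type, states = states, freqs = freqs, Q = Q,
                 V1 = diag(1 / d) %*% eig$vectors,
                 V2 = t(eig$vectors) %*% diag(d),
                 lambda = eig$values),
            class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site).
#' @return A stochastic matrix over the model's states.
#' @export
transition_matrix <- function(model, t) {
  P <- model$V1 %*% (exp(model$lambda * t) * model$V2)
  P[P < 0] <- 0
  P
}

#' Empirical residue frequencies of an alignment
#'
#' Gaps and ambiguity characters are ignored; a pseudocount keeps every
#' state's frequency positive.
#'
#' @param aln Named character vector of aligned sequences.
#' @param type `"nt"` or `"aa"`.
#' @return Frequency vector over the model states.
#' @export
residue_frequencies <- function(aln, type = c("nt", "aa")) {
  type <- match.arg(type)
  states <- if (type == "nt") DNA_BASES else AA_STATES
  ch <- unlist(strsplit(toupper(aln), ""), use.names = FALSE)
  counts <- table(factor(ch, levels = states)) + 1
  as.numeric(counts / sum(counts))
}
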