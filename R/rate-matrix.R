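#' Goldman-Yang codon rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix of the reversible
#' Goldman-Yang (GY94-style) codon model: substitutions touching more than
#' one codon position have rate zero, and a single-position change from
#' codon i to j has rate
#' \deqn{q_{ij} = \pi_j \, \kappa^{[transition]} \, \omega^{[nonsynonymous]}.}
#' The matrix is scaled so the mean substitution rate at stationarity is 1,
#' i.e. branch lengths are expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi Codon frequency vector over the 61 sense codons (sums to 1);
#'   defaults to equal frequencies.
#' @param code Genetic code.
#' @return Rate matrix with attributes `pi` and `rate_scale` (the mean rate
#'   of the unscaled matrix, used to convert between rate parameterizations).
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = NULL,
                             code = standard_genetic_code()) {
  stopifnot(is.finite(kappa), kappa >= 0, is.finite(omega), omega >= 0)
  n <- length(code$sense_codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  stopifnot(length(pi) == n, all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  pr <- .codon_pairs(code)
  Q <- matrix(0, n, n, dimnames = list(code$sense_codons, code$sense_codons))
  rate <- pi[pr$j] * ifelse(pr$transition, kappa, 1) *
    ifelse(pr$synonymous, 1, omega)
  Q[cbind(pr$i, pr$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  attr(Q, "pi") <- pi
  attr(Q, "rate_scale") <- scale
  Q
}

# eigendecomposition of the pi-symmetrized reversible rate matrix, packaged
# for the C++ pruning kernel: P(t) = A exp(lam t) B
.eigen_system <- function(Q) {
  pi <- attr(Q, "pi")
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / sp, B = t(e$vectors) * rep(sp, each = length(sp)),
       lam = e$values)
}

#' Transition probability matrix
#'
#' Computes `P(t) = exp(Qt)` via the eigendecomposition of the reversibility-
#' symmetrized rate matrix.
#'
#' @param Q A rate matrix from [gy94_rate_matrix()].
#' @param t Branch length (>= 0).
#' @return Row-stochastic matrix of the same dimension as `Q`.
#' @export
transition_probs <- function(Q, t) {
  if (t < 0) stop("value error: branch length must be non-negative")
  es <- .eigen_system(Q)
  P <- es$A %*% (exp(es$lam * t) * es$B)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}
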