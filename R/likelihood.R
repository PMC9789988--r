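#' @useDynLib ohnosel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Prepare the immutable parts of a likelihood computation: postorder edges,
# tip state matrix (patterns), pattern weights.
.likelihood_data <- function(aln, tree, code = standard_genetic_code()) {
  if (!setequal(tree$tip.label, aln$taxa))
    stop("identity error: alignment taxa and tree tip labels differ")
  states <- .codon_indices(aln, code)
  states <- states[match(tree$tip.label, aln$taxa), , drop = FALSE]
  pat <- .site_patterns(states)
  po <- ape::reorder.phylo(tree, "postorder")
  # carry foreground flags through the reordering by matching child nodes
  fg <- rep(FALSE, nrow(po$edge))
  if (!is.null(tree$foreground))
    fg <- tree$foreground[match(po$edge[, 2], tree$edge[, 2])]
  list(edge = po$edge, edge_length = po$edge.length, foreground = fg,
       n_tip = length(tree$tip.label),
       states = pat$states, weights = pat$weights, map = pat$map)
}

# Core likelihood: `eig` is a list of rate-class eigensystems, `class_w` an
# nedge x nclass weight matrix.
.prune <- function(ld, eig, class_w, edge_length = NULL) {
  st <- ld$states
  st[is.na(st)] <- 0L
  .cpp_prune_loglik(ld$edge, if (is.null(edge_length)) ld$edge_length else edge_length,
                    ld$n_tip, st, ld$weights,
                    attr(eig[[1]], "pi"), eig, class_w)
}

.eig_class <- function(Q) {
  es <- .eigen_system(Q)
  attr(es, "pi") <- attr(Q, "pi")
  es
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning likelihood under the GY94 model: the sum over sites
#' of the log of the pruned site likelihood, with the root weighted by the
#' stationary codon frequencies.  Missing codons (gaps, ambiguities)
#' contribute partial likelihoods of one.
#'
#' @param aln A [codon_alignment()].
#' @param tree A `phylo` with branch lengths in expected substitutions per
#'   codon; taxa must match the alignment.
#' @param kappa,omega GY94 parameters.  `omega` may be length 2
#'   (background, foreground) if the tree carries foreground flags.
#' @param pi Codon frequencies (default equal).
#' @param code Genetic code.
#' @return Log-likelihood (numeric scalar) with attribute `site_loglik`.
#' @export
log_likelihood <- function(aln, tree, kappa, omega, pi = NULL,
                           code = standard_genetic_code()) {
  ld <- .likelihood_data(aln, tree, code)
  nedge <- nrow(ld$edge)
  if (length(omega) == 1L) {
    eig <- list(.eig_class(gy94_rate_matrix(kappa, omega, pi, code)))
    cw <- matrix(1, nedge, 1)
  } else {
    eig <- list(.eig_class(gy94_rate_matrix(kappa, omega[1], pi, code)),
                .eig_class(gy94_rate_matrix(kappa, omega[2], pi, code)))
    cw <- cbind(!ld$foreground, ld$foreground) * 1
  }
  res <- .prune(ld, eig, cw)
  structure(res$loglik, site_loglik = res$pattern_loglik[ld$map])
}

# ---- R reference pruning with stored partials (ancestral reconstruction) ----

# P matrices per postorder edge under a single rate class
.edge_P <- function(ld, Q, edge_length = NULL) {
  el <- if (is.null(edge_length)) ld$edge_length else edge_length
  es <- .eigen_system(Q)
  lapply(el, function(t) {
    P <- es$A %*% (exp(es$lam * t) * es$B)
    P[P < 0] <- 0
    P
  })
}

# upward (pruning) partials for every node; no underflow scaling beyond
# double range -- intended for small to moderate problems
.pruning_up <- function(ld, Plist) {
  ns <- nrow(Plist[[1]])
  npat <- length(ld$weights)
  n_node <- max(ld$edge)
  up <- vector("list", n_node)
  tip_partial <- function(tip) {
    out <- matrix(1, ns, npat)
    s <- ld$states[tip, ]
    ok <- !is.na(s)
    out[, ok] <- 0
    out[cbind(s[ok], which(ok))] <- 1
    out
  }
  for (e in seq_len(nrow(ld$edge))) {
    parent <- ld$edge[e, 1]; child <- ld$edge[e, 2]
    Lc <- if (child <= ld$n_tip) tip_partial(child) else up[[child]]
    contrib <- Plist[[e]] %*% Lc
    up[[parent]] <- if (is.null(up[[parent]])) contrib else up[[parent]] * contrib
  }
  up
}
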