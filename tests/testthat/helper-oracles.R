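# Independent brute-force oracles used to validate the likelihood,
# counting, and scanning machinery on small fixtures.  These deliberately
# share no code with the implementation paths they check.

# Exhaustive-enumeration log-likelihood: sum over all internal-node codon
# assignments.  Feasible for <= 4 taxa.
enum_loglik <- function(aln, tree, kappa, omega, pi = NULL) {
  code <- standard_genetic_code()
  n <- length(code$sense_codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  Q <- gy94_rate_matrix(kappa, omega, pi)
  P <- lapply(tree$edge.length, function(t) transition_probs(Q, t))
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1L):max(tree$edge)
  root <- n_tip + 1L
  idx <- match(aln$codons, code$sense_codons)
  dim(idx) <- dim(aln$codons)
  idx <- idx[match(tree$tip.label, aln$taxa), , drop = FALSE]
  G <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internals))))
  colnames(G) <- internals
  total <- 0
  for (s in seq_len(aln$n_codons)) {
    p <- pi[G[, as.character(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      pstate <- G[, as.character(pa)]
      cstate <- if (ch <= n_tip) {
        tip <- idx[ch, s]
        if (is.na(tip)) NULL else rep(tip, nrow(G))
      } else G[, as.character(ch)]
      if (is.null(cstate)) next  # missing tip: marginalize (P rows sum to 1)
      p <- p * P[[e]][cbind(pstate, cstate)]
    }
    total <- total + log(sum(p))
  }
  total
}

# Marginal ML ancestral states by enumeration (posterior of each internal
# node marginalizing over the others), for <= 4 taxa.
enum_ancestral <- function(aln, tree, kappa, omega, pi = NULL) {
  code <- standard_genetic_code()
  n <- length(code$sense_codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  Q <- gy94_rate_matrix(kappa, omega, pi)
  P <- lapply(tree$edge.length, function(t) transition_probs(Q, t))
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1L):max(tree$edge)
  root <- n_tip + 1L
  idx <- match(aln$codons, code$sense_codons)
  dim(idx) <- dim(aln$codons)
  idx <- idx[match(tree$tip.label, aln$taxa), , drop = FALSE]
  G <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internals))))
  colnames(G) <- internals
  out <- matrix(NA_integer_, length(internals), aln$n_codons,
                dimnames = list(internals, NULL))
  for (s in seq_len(aln$n_codons)) {
    p <- pi[G[, as.character(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      pstate <- G[, as.character(pa)]
      cstate <- if (ch <= n_tip) {
        tip <- idx[ch, s]
        if (is.na(tip)) NULL else rep(tip, nrow(G))
      } else G[, as.character(ch)]
      if (is.null(cstate)) next
      p <- p * P[[e]][cbind(pstate, cstate)]
    }
    for (nd in internals) {
      marg <- tapply(p, G[, as.character(nd)], sum)
      out[as.character(nd), s] <- as.integer(names(marg)[which.max(marg)])
    }
  }
  out
}

# Independent syn/nonsyn step counter: breadth-first shortest paths in the
# single-nucleotide codon graph, stop codons removed; averages per-step
# synonymy over all shortest paths.
oracle_path_counts <- function(c1, c2) {
  code <- standard_genetic_code()
  sense <- code$sense_codons
  s1 <- sense[c1]; s2 <- sense[c2]
  if (s1 == s2) return(c(syn = 0, nonsyn = 0))
  nd <- sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  neighbours <- function(cd) {
    v <- strsplit(cd, "")[[1]]
    out <- character(0)
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == v[p]) next
      w <- v; w[p] <- b
      out <- c(out, paste(w, collapse = ""))
    }
    out[out %in% sense]
  }
  # enumerate all paths of length nd (shortest possible) from s1 to s2
  paths <- list(c(s1))
  for (step in seq_len(nd)) {
    paths <- unlist(lapply(paths, function(pp) {
      lapply(neighbours(pp[length(pp)]), function(nb) c(pp, nb))
    }), recursive = FALSE)
    # prune paths that cannot still reach s2 in the remaining steps
    paths <- Filter(function(pp) {
      left <- nd - step
      sum(strsplit(pp[length(pp)], "")[[1]] != strsplit(s2, "")[[1]]) <= left
    }, paths)
  }
  paths <- Filter(function(pp) pp[length(pp)] == s2, paths)
  if (!length(paths)) return(NULL)  # no stop-free shortest path
  aa <- function(cd) code$codon_to_aa[cd]
  counts <- vapply(paths, function(pp) {
    syn <- 0; nonsyn <- 0
    for (k in seq_len(length(pp) - 1)) {
      if (aa(pp[k]) == aa(pp[k + 1])) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    c(syn, nonsyn)
  }, numeric(2))
  c(syn = mean(counts[1, ]), nonsyn = mean(counts[2, ]))
}

# Brute-force window scan for LxxLAP
oracle_lxxlap <- function(s) {
  s <- toupper(s)
  hits <- integer(0)
  if (nchar(s) >= 6) {
    for (i in 1:(nchar(s) - 5)) {
      w <- substring(s, i, i + 5)
      ok <- substr(w, 1, 1) == "L" && substr(w, 4, 4) == "L" &&
        substr(w, 5, 5) == "A" && substr(w, 6, 6) == "P"
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# shared small fixtures
fixture_alignment <- function(n_taxa = 4, n_codons = 3, seed = 1,
                              omega = 0.4, kappa = 1.8) {
  tree <- sim_tree(n_taxa, seed = seed, min_branch = 0.05, max_branch = 0.3)
  sc <- sim_scenario(tree, kappa = kappa,
                     omega = list(type = "constant", omega = omega),
                     n_codons = n_codons, seed = seed + 1000)
  sim <- simulate_codon_alignment(sc)
  list(aln = sim$alignment, tree = tree, kappa = kappa, omega = omega)
}
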