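# Marginal maximum-likelihood ancestral codon states under a fitted M0
# model, via the standard up-down (inside-outside) algorithm on the pruning
# partials.

#' Marginal ancestral codon reconstruction
#'
#' @param aln A [codon_alignment()].
#' @param tree A `phylo` (typically the fitted tree from [codon_fit()]).
#' @param global_fit A [codon_fit()] supplying `kappa`, `pi` and, if `tree`
#'   is missing, the fitted branch lengths.
#' @return Integer matrix (internal nodes x sites) of codon state indices
#'   into `standard_genetic_code()$sense_codons`; rows named by ape node
#'   number.
#' @export
ancestral_reconstruction <- function(aln, tree = NULL, global_fit) {
  if (is.null(tree)) tree <- global_fit$tree
  code <- standard_genetic_code()
  ld <- .likelihood_data(aln, tree, code)
  omega <- unname(global_fit$omega[1])
  Q <- gy94_rate_matrix(global_fit$kappa, omega, global_fit$pi, code)
  Plist <- .edge_P(ld, Q)
  post <- .marginal_posteriors(ld, Plist, attr(Q, "pi"))
  n_tip <- ld$n_tip
  nodes <- (n_tip + 1L):max(ld$edge)
  states <- t(vapply(nodes, function(nd)
    apply(post[[nd]], 2, which.max)[ld$map], integer(length(ld$map))))
  rownames(states) <- nodes
  states
}

# posterior state distributions for internal nodes (patterns as columns)
.marginal_posteriors <- function(ld, Plist, pi) {
  nedge <- nrow(ld$edge)
  n_node <- max(ld$edge)
  ns <- length(pi)
  npat <- length(ld$weights)
  up <- vector("list", n_node)
  contrib <- vector("list", nedge)
  tip_partial <- function(tip) {
    out <- matrix(1, ns, npat)
    s <- ld$states[tip, ]
    ok <- !is.na(s)
    out[, ok] <- 0
    out[cbind(s[ok], which(ok))] <- 1
    out
  }
  for (e in seq_len(nedge)) {
    parent <- ld$edge[e, 1]; child <- ld$edge[e, 2]
    Lc <- if (child <= ld$n_tip) tip_partial(child) else up[[child]]
    contrib[[e]] <- Plist[[e]] %*% Lc
    up[[parent]] <- if (is.null(up[[parent]])) contrib[[e]] else
      up[[parent]] * contrib[[e]]
  }
  root <- ld$n_tip + 1L
  flow <- vector("list", n_node)
  flow[[root]] <- matrix(pi, ns, npat)
  for (e in rev(seq_len(nedge))) {       # preorder
    parent <- ld$edge[e, 1]; child <- ld$edge[e, 2]
    if (child <= ld$n_tip) next
    sibs <- setdiff(which(ld$edge[, 1] == parent), e)
    sib_prod <- flow[[parent]]
    for (s in sibs) sib_prod <- sib_prod * contrib[[s]]
    flow[[child]] <- crossprod(Plist[[e]], sib_prod)
  }
  post <- vector("list", n_node)
  for (nd in (ld$n_tip + 1L):n_node) {
    p <- up[[nd]] * flow[[nd]]
    cs <- colSums(p)
    cs[cs == 0] <- 1
    post[[nd]] <- sweep(p, 2, cs, "/")
  }
  post
}

# ---------------------------------------------------------------------------
# expected synonymous/nonsynonymous mutational opportunity per codon,
# kappa-weighted over single-nucleotide neighbours (stops excluded)
.codon_opportunity <- function(kappa, code = standard_genetic_code()) {
  pr <- .codon_pairs(code)
  w <- ifelse(pr$transition, kappa, 1)
  es <- en <- numeric(length(code$sense_codons))
  for (k in seq_along(pr$i)) {
    if (pr$synonymous[k]) es[pr$i[k]] <- es[pr$i[k]] + w[k]
    else en[pr$i[k]] <- en[pr$i[k]] + w[k]
  }
  list(es = es, en = en)
}

# average (syn, nonsyn) step counts over all shortest mutational paths
# between two codons that avoid stop codons; falls back to all paths if
# every shortest path crosses a stop
.path_changes <- function(ci, cj, code = standard_genetic_code()) {
  key <- paste0(ci, ":", cj)
  cache <- .ohnosel_cache
  if (is.null(cache$paths)) assign("paths", new.env(parent = emptyenv()),
                                   envir = cache)
  hit <- get0(key, envir = cache$paths)
  if (!is.null(hit)) return(hit)
  sense <- code$sense_codons
  a <- strsplit(sense[ci], "")[[1]]
  b <- strsplit(sense[cj], "")[[1]]
  diff <- which(a != b)
  count_path <- function(order) {
    cur <- a; syn <- 0; nonsyn <- 0; valid <- TRUE
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      c_cur <- paste(cur, collapse = ""); c_nxt <- paste(nxt, collapse = "")
      if (c_nxt %in% code$stop_codons) valid <- FALSE
      if (translate_codon(c_cur, code) == translate_codon(c_nxt, code))
        syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn, valid)
  }
  if (length(diff) == 0L) {
    res <- c(syn = 0, nonsyn = 0)
  } else {
    orders <- .permutations(diff)
    paths <- t(vapply(orders, count_path, numeric(3)))
    use <- paths[, 3] == 1
    if (!any(use)) use <- rep(TRUE, nrow(paths))
    res <- c(syn = mean(paths[use, 1]), nonsyn = mean(paths[use, 2]))
  }
  assign(key, res, envir = cache$paths)
  res
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

# generalized binomial tails allowing fractional counts
# P(Syn <= s | n, p): pbeta identity extended to real s, n
.binom_lower <- function(s, n, p) {
  if (n <= 0) return(1)
  if (s >= n - 1e-9) return(1)
  stats::pbeta(1 - p, n - s, s + 1)
}
.binom_upper <- function(s, n, p) {
  if (n <= 0) return(1)
  if (s <= 1e-9) return(1)
  stats::pbeta(p, s, n - s + 1)
}

#' Ancestor-counting (SLAC-style) site substitution counts
#'
#' Reconstructs ancestral codons by marginal maximum likelihood under the
#' global one-ratio fit, decomposes the implied substitutions on every
#' branch into synonymous and nonsynonymous changes (multi-nucleotide
#' changes averaged over all shortest stop-avoiding mutational paths), and
#' tests each site's synonymous fraction against its kappa-weighted neutral
#' expectation with binomial tail probabilities.
#'
#' @param aln A [codon_alignment()].
#' @param tree Optional `phylo`; defaults to the fitted tree in
#'   `global_fit`.
#' @param global_fit A [codon_fit()] (one-ratio).
#' @return Data frame of class `slac_counts`: `site`, `obs_syn`,
#'   `obs_nonsyn`, `expected_syn_fraction`, `p_positive`, `p_negative`,
#'   `untestable`.
#' @export
slac_site_counts <- function(aln, tree = NULL, global_fit) {
  if (is.null(tree)) tree <- global_fit$tree
  code <- standard_genetic_code()
  ld <- .likelihood_data(aln, tree, code)
  anc <- ancestral_reconstruction(aln, tree, global_fit)
  opp <- .codon_opportunity(global_fit$kappa, code)
  n_tip <- ld$n_tip
  n_sites <- aln$n_codons
  tip_states <- .codon_indices(aln, code)[match(tree$tip.label, aln$taxa), ,
                                          drop = FALSE]
  state_of <- function(node, site) {
    if (node <= n_tip) tip_states[node, site]
    else anc[as.character(node), site]
  }
  obs_syn <- obs_nonsyn <- exp_es <- exp_en <- numeric(n_sites)
  untestable <- logical(n_sites)
  for (s in seq_len(n_sites)) {
    if (all(is.na(tip_states[, s]))) { untestable[s] <- TRUE; next }
    for (e in seq_len(nrow(ld$edge))) {
      pa <- state_of(ld$edge[e, 1], s)
      ch <- state_of(ld$edge[e, 2], s)
      if (is.na(pa) || is.na(ch)) next
      if (pa != ch) {
        pc <- .path_changes(pa, ch, code)
        obs_syn[s] <- obs_syn[s] + pc["syn"]
        obs_nonsyn[s] <- obs_nonsyn[s] + pc["nonsyn"]
      }
      exp_es[s] <- exp_es[s] + opp$es[pa]
      exp_en[s] <- exp_en[s] + opp$en[pa]
    }
  }
  frac <- ifelse(exp_es + exp_en > 0, exp_es / (exp_es + exp_en), NA_real_)
  n_tot <- obs_syn + obs_nonsyn
  p_pos <- p_neg <- rep(1, n_sites)
  for (s in seq_len(n_sites)) {
    if (untestable[s] || is.na(frac[s]) || n_tot[s] == 0) next
    p_pos[s] <- .binom_lower(obs_syn[s], n_tot[s], frac[s])
    p_neg[s] <- .binom_upper(obs_syn[s], n_tot[s], frac[s])
  }
  out <- data.frame(site = seq_len(n_sites), obs_syn = obs_syn,
                    obs_nonsyn = obs_nonsyn, expected_syn_fraction = frac,
                    p_positive = p_pos, p_negative = p_neg,
                    untestable = untestable)
  class(out) <- c("slac_counts", "data.frame")
  out
}
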