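#' Random tree for simulation studies
#'
#' A seeded random topology with branch lengths uniform on
#' `[0.05, 0.35]` expected substitutions per codon -- a desk-scale stand-in
#' for a deeply diverged gene-family tree (the regime of cross-lineage
#' paralog alignments with a distant outgroup).
#'
#' @param n_taxa Number of tips.
#' @param seed Integer seed.
#' @param min_branch,max_branch Branch-length range.
#' @return A `phylo`.
#' @export
sim_tree <- function(n_taxa, seed, min_branch = 0.05, max_branch = 0.35) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa)
  tree$edge.length <- stats::runif(nrow(tree$edge), min_branch, max_branch)
  tree
}

#' Codon-simulation scenario
#'
#' Bundles everything [simulate_codon_alignment()] needs.  The `omega`
#' regime is one of:
#' \itemize{
#' \item `list(type = "constant", omega = )` -- one ratio everywhere;
#' \item `list(type = "site_classes", omega = c(...), weights = c(...))` --
#'   each site draws its ratio from a discrete distribution;
#' \item `list(type = "branch", omega_background = , omega_foreground = )` --
#'   two-ratio: flagged branches use the foreground ratio at every site;
#' \item `list(type = "episodic", omega_background = , omega_plus = ,
#'   site_fraction = )` -- a random fraction of sites uses `omega_plus` on
#'   the tree's flagged foreground branches;
#' \item `list(type = "branch_site", omega_background = , omega_plus = ,
#'   branch_fraction = )` -- per site, each branch independently uses
#'   `omega_plus` with the given probability (episodic selection on a
#'   proportion of branches).
#' }
#'
#' @param tree A `phylo` (with foreground flags for the branch regimes).
#' @param kappa Transition/transversion ratio.
#' @param omega Omega regime (see above).
#' @param pi Codon frequencies (default equal).
#' @param n_codons Alignment length in codons.
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(tree, kappa, omega, pi = NULL, n_codons, seed) {
  stopifnot(!missing(seed), is.numeric(seed))
  if (is.null(omega$type)) stop("omega regime needs a 'type'")
  if (identical(omega$type, "site_classes")) {
    stopifnot(abs(sum(omega$weights) - 1) < 1e-8,
              length(omega$weights) == length(omega$omega))
  }
  structure(list(tree = tree, kappa = kappa, omega = omega, pi = pi,
                 n_codons = as.integer(n_codons), seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a codon alignment under a GY94 regime
#'
#' The root sequence is drawn from the stationary codon frequencies and
#' evolved branch by branch using the model's transition probabilities.
#' Deterministic given the scenario seed; the per-site/per-branch omega
#' assignments are returned as a machine-readable truth record.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `alignment` (a [codon_alignment()]) and `truth`
#'   (scenario parameters plus realized site/branch assignments).
#' @export
simulate_codon_alignment <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  code <- standard_genetic_code()
  tree <- scenario$tree
  L <- scenario$n_codons
  n <- length(code$sense_codons)
  pi <- if (is.null(scenario$pi)) rep(1 / n, n) else scenario$pi
  reg <- scenario$omega

  po <- ape::reorder.phylo(tree, "postorder")
  fg <- rep(FALSE, nrow(po$edge))
  if (!is.null(tree$foreground))
    fg <- tree$foreground[match(po$edge[, 2], tree$edge[, 2])]
  nedge <- nrow(po$edge)

  # per-site background class and realized assignments
  site_omega <- rep(NA_real_, L)
  affected_sites <- logical(L)
  omegas <- switch(reg$type,
    constant = reg$omega,
    site_classes = reg$omega,
    branch = c(reg$omega_background, reg$omega_foreground),
    episodic = c(reg$omega_background, reg$omega_plus),
    branch_site = c(reg$omega_background, reg$omega_plus),
    stop("unknown omega regime: ", reg$type))
  site_class <- switch(reg$type,
    constant = rep(1L, L),
    site_classes = sample.int(length(reg$omega), L, TRUE, prob = reg$weights),
    branch = rep(1L, L),
    episodic = { affected_sites <- stats::runif(L) < reg$site_fraction
                 rep(1L, L) },
    branch_site = rep(1L, L))
  site_omega <- omegas[site_class]

  # Rate-class scaling.  The branch-model regimes ("constant", "branch")
  # use per-class mean-rate-1 matrices, matching the branch-model
  # parameterization where branch lengths are expected substitutions under
  # that branch's own omega.  The site-level regimes keep the synonymous
  # rate constant across classes (matrices share the omega = 1 scale), so
  # an elevated omega means genuinely more nonsynonymous events -- the
  # signature the site tests are built to detect.
  share_syn_scale <- reg$type %in% c("site_classes", "episodic", "branch_site")
  mult <- rep(1, length(omegas))
  if (share_syn_scale) {
    C1 <- attr(gy94_rate_matrix(scenario$kappa, 1, pi, code), "rate_scale")
    mult <- vapply(omegas, function(w)
      attr(gy94_rate_matrix(scenario$kappa, w, pi, code), "rate_scale") / C1,
      numeric(1))
  }
  eig <- lapply(omegas, function(w)
    .eig_class(gy94_rate_matrix(scenario$kappa, w, pi, code)))

  n_node <- max(po$edge)
  states <- matrix(NA_integer_, n_node, L)
  root <- length(tree$tip.label) + 1L
  states[root, ] <- sample.int(n, L, TRUE, prob = pi)

  evolve <- function(parent_states, P, sites) {
    out <- integer(length(sites))
    for (u in unique(parent_states)) {
      idx <- which(parent_states == u)
      out[idx] <- sample.int(n, length(idx), TRUE, prob = P[u, ])
    }
    out
  }

  branch_site_draws <- if (reg$type == "branch_site")
    matrix(stats::runif(nedge * L) < reg$branch_fraction, nedge, L) else NULL

  for (e in rev(seq_len(nedge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    t_e <- po$edge.length[e]
    # per-site class on this edge
    cls <- site_class
    if (reg$type %in% c("branch", "episodic") && fg[e]) {
      cls <- if (reg$type == "branch") rep(2L, L) else
        ifelse(affected_sites, 2L, 1L)
    } else if (reg$type == "branch_site") {
      cls <- ifelse(branch_site_draws[e, ], 2L, 1L)
    }
    child_states <- integer(L)
    for (k in unique(cls)) {
      es <- eig[[k]]
      P <- es$A %*% (exp(es$lam * t_e * mult[k]) * es$B)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      idx <- which(cls == k)
      child_states[idx] <- evolve(states[parent, idx], P, idx)
    }
    states[child, ] <- child_states
  }

  tips <- states[seq_along(tree$tip.label), , drop = FALSE]
  codons <- matrix(code$sense_codons[tips], nrow = nrow(tips),
                   dimnames = list(tree$tip.label, NULL))
  aln <- codon_alignment(codons, code, allow_stops = TRUE)
  truth <- list(regime = reg, kappa = scenario$kappa, pi = pi,
                seed = scenario$seed, site_omega = site_omega,
                affected_sites = affected_sites,
                foreground_edges = which(fg),
                branch_site_draws = branch_site_draws)
  list(alignment = aln, truth = truth)
}

# ---------------------------------------------------------------------------
# Post-WGD gene-neighborhood simulator

#' Neighborhood-evolution scenario
#'
#' Emulates the history used for synteny-based ohnolog naming: an ancestral
#' window of flanking genes is duplicated by a whole-genome duplication and
#' each descendant copy (plus an unduplicated sister-lineage reference)
#' independently loses genes, flips strands, and gains novel insertions.
#'
#' @param window Flank slots per side (default 10).
#' @param loss_prob Per-gene loss probability for the two duplicated copies
#'   (length 1 or 2; loss replaces the ancestral gene by a novel symbol).
#' @param ref_loss_prob Loss probability on the sister-reference branch.
#' @param inversion_prob Per-gene strand-flip probability.
#' @param insertion_rate Expected number of novel insertions per side.
#' @param seed Mandatory integer seed.
#' @return Object of class `neighborhood_scenario`.
#' @export
neighborhood_scenario <- function(window = 10, loss_prob = 0.2,
                                  ref_loss_prob = 0.1,
                                  inversion_prob = 0.05,
                                  insertion_rate = 0, seed) {
  stopifnot(!missing(seed))
  if (length(loss_prob) == 1L) loss_prob <- rep(loss_prob, 2)
  stopifnot(all(loss_prob >= 0 & loss_prob <= 1),
            ref_loss_prob >= 0, ref_loss_prob <= 1)
  structure(list(window = as.integer(window), loss_prob = loss_prob,
                 ref_loss_prob = ref_loss_prob,
                 inversion_prob = inversion_prob,
                 insertion_rate = insertion_rate, seed = as.integer(seed)),
            class = "neighborhood_scenario")
}

#' Simulate post-WGD gene neighborhoods
#'
#' @param scenario A [neighborhood_scenario()].
#' @return List with `ancestor`, `copy1`, `copy2`, `reference` (all
#'   [gene_neighborhood()] objects) and `truth` (realized retained-gene
#'   counts per copy).
#' @export
simulate_neighborhoods <- function(scenario) {
  stopifnot(inherits(scenario, "neighborhood_scenario"))
  set.seed(scenario$seed)
  w <- scenario$window
  offsets <- c(-(w:1), 1:w)
  anc_sym <- sprintf("ANC%02d", seq_len(2 * w))
  anc_str <- sample(c("+", "-"), 2 * w, TRUE)
  novel <- local({ i <- 0L; function(n) {
    i <<- i + n; sprintf("NOV%04d", seq(i - n + 1L, i)) } })
  ancestor <- gene_neighborhood("ancestor", "FOCAL", offsets, anc_sym, anc_str)

  mutate <- function(species, p_loss) {
    sym <- anc_sym; str <- anc_str
    lost <- stats::runif(2 * w) < p_loss
    sym[lost] <- novel(sum(lost))
    flip <- stats::runif(2 * w) < scenario$inversion_prob
    str[flip] <- ifelse(str[flip] == "+", "-", "+")
    if (scenario$insertion_rate > 0) {
      for (side in c(-1, 1)) {
        k <- stats::rpois(1, scenario$insertion_rate)
        if (k > 0) {
          sel <- which(sign(offsets) == side)
          pos <- sample(seq_along(sel), min(k, length(sel)))
          # an insertion displaces the slot it lands on (window is fixed width)
          sym[sel[pos]] <- novel(length(pos))
          str[sel[pos]] <- sample(c("+", "-"), length(pos), TRUE)
        }
      }
    }
    list(nb = gene_neighborhood(species, "FOCAL", offsets, sym, str),
         retained = sum(sym %in% anc_sym))
  }

  c1 <- mutate("copy1", scenario$loss_prob[1])
  c2 <- mutate("copy2", scenario$loss_prob[2])
  rf <- mutate("reference", scenario$ref_loss_prob)
  list(ancestor = ancestor, copy1 = c1$nb, copy2 = c2$nb,
       reference = rf$nb,
       truth = list(retained = c(copy1 = c1$retained, copy2 = c2$retained,
                                 reference = rf$retained),
                    loss_prob = scenario$loss_prob,
                    seed = scenario$seed))
}

# ---------------------------------------------------------------------------
# Negative-binomial expression simulator

#' Expression-simulation scenario
#'
#' Negative-binomial counts per gene x tissue with a paralog x tissue mean
#' matrix shared across species, plus background genes so that TPM can be
#' normalized over a full transcriptome.
#'
#' @param species Character vector of species names.
#' @param mean_matrix Numeric paralog x tissue matrix of expected counts.
#' @param presence Optional logical species x paralog matrix (a `FALSE`
#'   entry means that species lacks the paralog; default all present).
#' @param dispersion Negative-binomial size parameter; `Inf` gives Poisson.
#' @param n_background Number of background genes per species.
#' @param background_mean Log-normal mean parameter for background counts.
#' @param seed Mandatory integer seed.
#' @return Object of class `expression_scenario`.
#' @export
expression_scenario <- function(species, mean_matrix, presence = NULL,
                                dispersion = 10, n_background = 200,
                                background_mean = 4, seed) {
  stopifnot(!missing(seed), all(mean_matrix >= 0), dispersion > 0)
  if (is.null(presence))
    presence <- matrix(TRUE, length(species), nrow(mean_matrix),
                       dimnames = list(species, rownames(mean_matrix)))
  structure(list(species = species, mean_matrix = mean_matrix,
                 presence = presence, dispersion = dispersion,
                 n_background = as.integer(n_background),
                 background_mean = background_mean, seed = as.integer(seed)),
            class = "expression_scenario")
}

#' Simulate RNA-seq count tables
#'
#' @param scenario An [expression_scenario()].
#' @return List of data frames: `counts` (species, gene, tissue, count),
#'   `lengths` (gene, length_kb), `paralog_map` (species, gene, paralog),
#'   and `truth`.
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "expression_scenario"))
  set.seed(scenario$seed)
  mm <- scenario$mean_matrix
  tissues <- colnames(mm)
  paralogs <- rownames(mm)
  draw <- function(mu, n) {
    if (is.infinite(scenario$dispersion)) stats::rpois(n, mu)
    else stats::rnbinom(n, size = scenario$dispersion, mu = mu)
  }
  counts <- list(); lengths <- list(); pmap <- list()
  for (sp in scenario$species) {
    present <- paralogs[scenario$presence[sp, ]]
    genes <- paste(sp, present, sep = "_")
    bg <- sprintf("%s_bg%04d", sp, seq_len(scenario$n_background))
    bg_mu <- stats::rlnorm(scenario$n_background, scenario$background_mean, 1)
    all_genes <- c(genes, bg)
    lengths[[sp]] <- data.frame(gene = all_genes,
                                length_kb = stats::rlnorm(length(all_genes),
                                                          0.5, 0.4))
    pmap[[sp]] <- data.frame(species = sp, gene = genes, paralog = present,
                             stringsAsFactors = FALSE)
    for (ts in tissues) {
      mu <- c(mm[present, ts], bg_mu)
      counts[[paste(sp, ts)]] <- data.frame(
        species = sp, gene = all_genes, tissue = ts,
        count = draw(mu, length(mu)), stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, c(counts, make.row.names = FALSE)),
       lengths = do.call(rbind, c(lengths, make.row.names = FALSE)),
       paralog_map = do.call(rbind, c(pmap, make.row.names = FALSE)),
       truth = list(mean_matrix = mm, presence = scenario$presence,
                    dispersion = scenario$dispersion, seed = scenario$seed))
}
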