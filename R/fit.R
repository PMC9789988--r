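#' Fit a branch codon model by maximum likelihood
#'
#' Fits the one-ratio model (a single dN/dS ratio `omega` for the whole
#' tree, "M0") or the two-ratio branch model (a background ratio `omega0`
#' and a foreground ratio `omega1` on the branches flagged by
#' [read_newick()]/[flag_foreground_clade()]) under the GY94 codon model.
#' `kappa`, the omega ratio(s), and either every branch length or a single
#' tree-scale factor are optimized jointly by bounded quasi-Newton
#' (L-BFGS-B) with seeded random restarts; codon frequencies are taken from
#' the data under the chosen frequency model and held fixed.
#'
#' @param aln A [codon_alignment()].
#' @param tree A `phylo`; for `model = "two-ratio"` it must carry at least
#'   one foreground and one background branch.
#' @param model `"M0"` (one ratio) or `"two-ratio"`.
#' @param freq_model Codon frequency model: `"F3x4"` (position-specific
#'   nucleotide frequencies, default), `"F1x4"`, or `"equal"`.
#' @param optimize_branch_lengths If `TRUE` (default) all branch lengths are
#'   free parameters; if `FALSE` the input lengths are fixed up to a single
#'   optimized scale factor (fast mode, used for large simulation studies).
#' @param n_starts Number of optimizer starts (first from neutral defaults,
#'   the rest seeded random perturbations).
#' @param seed Integer seed making the fit deterministic.
#' @param control Optional list: `factr`, `maxit` passed to [stats::optim()].
#' @return An object of class `codon_fit` with components `model`, `kappa`,
#'   `omega` (named vector), `pi`, `lnL`, `tree` (fitted branch lengths),
#'   `converged`, `n_iterations`, `np` (free parameters), `n_codons`.
#' @seealso [likelihood_ratio_test()], [branch_model_test()]
#' @examples
#' \donttest{
#' sc <- sim_scenario(sim_tree(8, seed = 1), kappa = 2,
#'                    omega = list(type = "constant", omega = 0.3),
#'                    n_codons = 100, seed = 1)
#' sim <- simulate_codon_alignment(sc)
#' fit <- codon_fit(sim$alignment, sc$tree, model = "M0", n_starts = 1, seed = 1)
#' coef(fit)
#' }
#' @export
codon_fit <- function(aln, tree, model = c("M0", "two-ratio"),
                      freq_model = c("F3x4", "F1x4", "equal"),
                      optimize_branch_lengths = TRUE,
                      n_starts = 3, seed = NULL, control = list()) {
  model <- match.arg(model)
  freq_model <- match.arg(freq_model)
  code <- standard_genetic_code()
  pi <- .codon_frequencies(aln, freq_model, code)
  ld <- .likelihood_data(aln, tree, code)
  nedge <- nrow(ld$edge)
  if (model == "two-ratio") {
    nfg <- sum(ld$foreground)
    if (nfg == 0L) stop("configuration error: no foreground branch flagged")
    if (nfg == nedge) stop("configuration error: all branches foreground")
    cw <- cbind(1 - ld$foreground, ld$foreground * 1)
  } else {
    cw <- matrix(1, nedge, 1)
  }
  n_omega <- if (model == "M0") 1L else 2L
  el0 <- pmax(ld$edge_length, 1e-4)      # start values for free lengths
  el_fixed <- pmax(ld$edge_length, 1e-8) # fast mode keeps input lengths

  neg_ll <- function(par) {
    kappa <- exp(par[1])
    omega <- exp(par[2:(1 + n_omega)])
    rest <- par[-seq_len(1 + n_omega)]
    el <- if (optimize_branch_lengths) exp(rest) else el_fixed * exp(rest)
    eig <- lapply(omega, function(w)
      .eig_class(gy94_rate_matrix(kappa, w, pi, code)))
    -.prune(ld, eig, cw, edge_length = el)$loglik
  }

  base_start <- c(log(2), rep(log(0.3), n_omega),
                  if (optimize_branch_lengths) log(el0) else 0)
  n_bl <- length(base_start) - 1L - n_omega
  lower <- c(log(1e-2), rep(log(1e-4), n_omega), rep(log(1e-7), n_bl))
  upper <- c(log(100), rep(log(50), n_omega),
             if (optimize_branch_lengths) rep(log(50), n_bl) else log(1e3))
  if (!optimize_branch_lengths) lower[length(lower)] <- log(1e-3)

  ctl <- list(factr = 1e7, maxit = 500)
  ctl[names(control)] <- control
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  n_eval <- 0L
  for (s in seq_len(max(1L, n_starts))) {
    start <- if (s == 1L) base_start else
      pmin(pmax(base_start + stats::rnorm(length(base_start), 0, 0.7), lower), upper)
    opt <- tryCatch(
      stats::optim(start, neg_ll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = ctl$factr, maxit = ctl$maxit)),
      error = function(e) NULL)
    if (is.null(opt)) next
    n_eval <- n_eval + opt$counts[1]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed in every start")

  par <- best$par
  kappa <- exp(par[1])
  omega <- exp(par[2:(1 + n_omega)])
  names(omega) <- if (model == "M0") "omega" else c("omega0", "omega1")
  rest <- par[-seq_len(1 + n_omega)]
  el_fit <- if (optimize_branch_lengths) exp(rest) else el_fixed * exp(rest)
  fitted_tree <- tree
  fitted_tree$edge.length <- el_fit[match(tree$edge[, 2], ld$edge[, 2])]
  converged <- best$convergence == 0
  notes <- character(0)
  if (model == "two-ratio" && sum(el_fit[ld$foreground]) < 1e-5) {
    converged <- FALSE
    notes <- "foreground branch lengths ~0: omega1 not identifiable"
  }
  structure(list(model = model, kappa = kappa, omega = omega, pi = pi,
                 freq_model = freq_model, lnL = -best$value,
                 tree = fitted_tree,
                 optimize_branch_lengths = optimize_branch_lengths,
                 scale = if (!optimize_branch_lengths) exp(rest) else NA_real_,
                 converged = converged, n_iterations = n_eval,
                 np = length(par), n_codons = aln$n_codons,
                 n_starts = n_starts, seed = seed, notes = notes,
                 call = match.call()),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("GY94 %s fit: lnL = %.4f%s\n", x$model, x$lnL,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  kappa = %.4f;  %s;  freq model %s\n", x$kappa,
              paste(sprintf("%s = %.4f", names(x$omega), x$omega),
                    collapse = ", "), x$freq_model))
  if (length(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' @export
coef.codon_fit <- function(object, ...) {
  c(kappa = unname(object$kappa), object$omega)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, nobs = object$n_codons,
            class = "logLik")
}

#' @export
summary.codon_fit <- function(object, ...) {
  structure(list(fit = object,
                 tree_length = sum(object$tree$edge.length)),
            class = "summary.codon_fit")
}

#' @export
print.summary.codon_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  tree length = %.4f expected substitutions/codon; %d free parameters\n",
              x$tree_length, x$fit$np))
  invisible(x)
}

#' Plot a fitted codon model
#'
#' Draws the fitted tree (branch lengths as estimated), highlighting
#' foreground branches for the two-ratio model, with the parameter
#' estimates in the title.
#'
#' @param x A [codon_fit()] result.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.codon_fit <- function(x, ...) {
  cols <- rep("black", nrow(x$tree$edge))
  if (!is.null(x$tree$foreground)) cols[x$tree$foreground] <- "firebrick"
  ape::plot.phylo(x$tree, edge.color = cols, ...)
  graphics::title(main = sprintf("%s: %s", x$model,
                                 paste(sprintf("%s = %.3f", names(x$omega),
                                               x$omega), collapse = ", ")))
  invisible(x)
}

#' Simulate alignments from a fitted codon model
#'
#' @param object A [codon_fit()] result.
#' @param nsim Number of alignments.
#' @param seed Integer seed.
#' @param n_codons Length of the simulated alignments (defaults to the
#'   length of the fitted data).
#' @param ... Unused.
#' @return A list of `nsim` simulation results (see
#'   [simulate_codon_alignment()]).
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = NULL,
                               n_codons = NULL, ...) {
  if (is.null(n_codons)) n_codons <- object$n_codons
  if (is.null(seed)) seed <- 1L
  regime <- if (object$model == "M0") {
    list(type = "constant", omega = unname(object$omega))
  } else {
    list(type = "branch", omega_background = unname(object$omega["omega0"]),
         omega_foreground = unname(object$omega["omega1"]))
  }
  lapply(seq_len(nsim), function(i) {
    sc <- sim_scenario(object$tree, kappa = object$kappa, omega = regime,
                       pi = object$pi, n_codons = n_codons,
                       seed = seed + i - 1L)
    simulate_codon_alignment(sc)
  })
}

#' Likelihood-ratio test between nested codon-model fits
#'
#' @param null,alt Fitted models from [codon_fit()] (or any objects with
#'   `lnL` and `np`); `alt` must nest `null`.
#' @param df Degrees of freedom; defaults to the difference in free
#'   parameter counts, and is 1 for the two-ratio vs one-ratio comparison.
#' @param mixture Optional numeric vector of weights over chi-squared
#'   degrees of freedom `0:(length(mixture)-1)` replacing the plain
#'   chi-squared reference.
#' @return Object of class `codon_lrt`: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(null, alt, df = NULL, mixture = NULL) {
  stat <- 2 * (alt$lnL - null$lnL)
  if (stat < -1e-6 * max(1, abs(null$lnL)))
    stop("nesting error: alternative lnL below null lnL (optimizer failure?)")
  stat <- max(stat, 0)
  if (is.null(df)) {
    df <- if (!is.null(alt$np) && !is.null(null$np)) alt$np - null$np else 1L
  }
  p <- .chisq_mix_pvalue(stat, df, mixture)
  structure(list(statistic = stat, df = df, mixture = mixture, p_value = p),
            class = "codon_lrt")
}

.chisq_mix_pvalue <- function(stat, df, mixture = NULL) {
  if (is.null(mixture)) return(stats::pchisq(stat, df, lower.tail = FALSE))
  mixture <- mixture / sum(mixture)
  dfs <- seq_along(mixture) - 1L
  sum(vapply(seq_along(mixture), function(k) {
    if (dfs[k] == 0L) mixture[k] * as.numeric(stat <= 1e-12)
    else mixture[k] * stats::pchisq(stat, dfs[k], lower.tail = FALSE)
  }, numeric(1)))
}

#' @export
print.codon_lrt <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f, df = %s, p = %.4g\n", x$statistic,
              paste(x$df, collapse = "/"), x$p_value))
  invisible(x)
}

#' One-ratio vs two-ratio branch-model comparison
#'
#' Convenience wrapper reproducing the classic branch-model analysis: fit
#' the one-ratio model and the two-ratio model with the flagged foreground,
#' compare them by a 1-df likelihood-ratio test, and tabulate the result
#' (model, -lnL, parameter estimates, LRT p).
#'
#' @inheritParams codon_fit
#' @param foreground Optional tip label vector defining the foreground
#'   clade (passed to [flag_foreground_clade()]); if `NULL` the tree's own
#'   flags are used.
#' @param ... Passed to [codon_fit()].
#' @return Object of class `branch_test` with the two fits, the
#'   [likelihood_ratio_test()], and a `table` data frame.
#' @export
branch_model_test <- function(aln, tree, foreground = NULL, ...) {
  if (!is.null(foreground)) tree <- flag_foreground_clade(tree, foreground)
  m0 <- codon_fit(aln, tree, model = "M0", ...)
  m2 <- codon_fit(aln, tree, model = "two-ratio", ...)
  lrt <- likelihood_ratio_test(m0, m2, df = 1)
  tab <- data.frame(
    model = c("Two-ratio", "M0"),
    minus_lnL = c(-m2$lnL, -m0$lnL),
    estimates = c(sprintf("omega0 = %.4f, omega1 = %.4f",
                          m2$omega["omega0"], m2$omega["omega1"]),
                  sprintf("omega = %.4f", m0$omega)),
    lrt_p = c(lrt$p_value, NA),
    stringsAsFactors = FALSE)
  structure(list(m0 = m0, two_ratio = m2, lrt = lrt, table = tab),
            class = "branch_test")
}

#' @export
print.branch_test <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a branch-model fit report as TSV
#'
#' @param x A [branch_model_test()] result.
#' @param path Output path.
#' @export
write_fit_report <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
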