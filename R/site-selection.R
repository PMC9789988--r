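# Site-level and gene-wide selection tests.  All of them condition on the
# global one-ratio fit: branch lengths, kappa, and codon frequencies are
# fixed, and per-site synonymous (alpha) and nonsynonymous (beta) rate
# multipliers are estimated by maximum likelihood.
#
# Key identity used throughout: with Rs/Rn the synonymous/nonsynonymous
# parts of the unscaled GY94 matrix,
#   Q(alpha, beta) = (alpha Rs + beta Rn) / C_global
#                  = alpha * (C_w / C_global) * Qnorm(w),  w = beta/alpha,
# so a single eigendecomposition per distinct omega suffices and alpha
# folds into the branch lengths (through the eigenvalues).

.site_test_setup <- function(aln, tree, global_fit,
                             code = standard_genetic_code()) {
  if (is.null(tree)) tree <- global_fit$tree
  ld <- .likelihood_data(aln, tree, code)
  kappa <- global_fit$kappa
  pi <- global_fit$pi
  Qg <- gy94_rate_matrix(kappa, unname(global_fit$omega[1]), pi, code)
  Q1 <- gy94_rate_matrix(kappa, 1, pi, code)
  eig1 <- .eig_class(Q1)
  list(ld = ld, kappa = kappa, pi = pi, code = code,
       C_glob = attr(Qg, "rate_scale"),
       eig1 = eig1, C1 = attr(Q1, "rate_scale"))
}

# eigensystem for rate class omega with total multiplier alpha, eigenvalues
# pre-scaled so the pruning kernel can use the unmodified branch lengths
.scaled_eig <- function(su, omega, alpha) {
  if (abs(omega - 1) < 1e-12) {
    es <- su$eig1
    es$lam <- es$lam * (alpha * su$C1 / su$C_glob)
    return(es)
  }
  Q <- gy94_rate_matrix(su$kappa, omega, su$pi, su$code)
  es <- .eig_class(Q)
  es$lam <- es$lam * (alpha * attr(Q, "rate_scale") / su$C_glob)
  es
}

.pattern_ld <- function(su, pat) {
  ld <- su$ld
  ld$states <- ld$states[, pat, drop = FALSE]
  ld$weights <- 1
  ld$map <- 1L
  ld
}

.pattern_invariant <- function(su, pat) {
  s <- su$ld$states[, pat]
  s <- s[!is.na(s)]
  length(unique(s)) <= 1L
}

.LOG_LOWER <- log(1e-4)
.LOG_UPPER <- log(100)

.fel_fit_pattern <- function(su, pat) {
  if (.pattern_invariant(su, pat)) {
    all_missing <- all(is.na(su$ld$states[, pat]))
    return(list(alpha = NA_real_, beta = NA_real_, statistic = 0,
                p_value = 1,
                classification = if (all_missing) "untestable" else "neutral",
                lnl_alt = NA_real_, lnl_null = NA_real_))
  }
  ldp <- .pattern_ld(su, pat)
  cw1 <- matrix(1, nrow(ldp$edge), 1)
  nll_null <- function(lr)
    -.prune(ldp, list(.scaled_eig(su, 1, exp(lr))), cw1)$loglik
  on <- stats::optimize(nll_null, c(.LOG_LOWER, .LOG_UPPER))
  nll_alt <- function(p)
    -.prune(ldp, list(.scaled_eig(su, exp(p[2] - p[1]), exp(p[1]))),
            cw1)$loglik
  best <- NULL
  for (st in list(c(on$minimum, on$minimum),
                  c(on$minimum, on$minimum + log(4)))) {
    o <- stats::optim(st, nll_alt, method = "L-BFGS-B",
                      lower = rep(.LOG_LOWER, 2), upper = rep(.LOG_UPPER, 2),
                      control = list(factr = 1e9))
    if (is.null(best) || o$value < best$value) best <- o
  }
  stat <- max(0, 2 * (on$objective - best$value))
  list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
       statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       lnl_alt = -best$value, lnl_null = -on$objective)
}

#' Fixed-effects likelihood (FEL-style) test of pervasive selection
#'
#' Per site, the synonymous rate `alpha` and nonsynonymous rate `beta` are
#' estimated by maximum likelihood with branch lengths, kappa, and codon
#' frequencies fixed at the global one-ratio fit; the null constrains
#' `alpha = beta` and the models are compared by a 1-df likelihood-ratio
#' test.
#'
#' @param aln A [codon_alignment()].
#' @param tree Optional `phylo`; defaults to the fitted tree.
#' @param site 1-based MSA codon.
#' @param global_fit A [codon_fit()].
#' @param p_threshold Significance threshold used for the classification
#'   (default 0.05).
#' @return One-row data frame: `site`, `alpha`, `beta`, `lrt_statistic`,
#'   `p_value`, `classification` (`positive`/`negative`/`neutral`/
#'   `untestable`).
#' @export
fel_site_test <- function(aln, tree = NULL, site, global_fit,
                          p_threshold = 0.05) {
  fel_scan(aln, tree, global_fit, sites = site, p_threshold = p_threshold)
}

#' @rdname fel_site_test
#' @param sites Sites to test (default all).
#' @export
fel_scan <- function(aln, tree = NULL, global_fit, sites = NULL,
                     p_threshold = 0.05) {
  su <- .site_test_setup(aln, tree, global_fit)
  if (is.null(sites)) sites <- seq_len(aln$n_codons)
  pats <- unique(su$ld$map[sites])
  fits <- lapply(pats, function(p) .fel_fit_pattern(su, p))
  idx <- match(su$ld$map[sites], pats)
  out <- do.call(rbind, lapply(seq_along(sites), function(k) {
    f <- fits[[idx[k]]]
    cls <- if (!is.null(f$classification)) f$classification else {
      if (f$p_value <= p_threshold && f$beta > f$alpha) "positive"
      else if (f$p_value <= p_threshold && f$beta < f$alpha) "negative"
      else "neutral"
    }
    data.frame(site = sites[k], alpha = f$alpha, beta = f$beta,
               lrt_statistic = f$statistic, p_value = f$p_value,
               lnl_alt = f$lnl_alt,
               classification = cls, stringsAsFactors = FALSE)
  }))
  class(out) <- c("site_test", "data.frame")
  attr(out, "test") <- "FEL"
  out
}

.meme_fit_pattern <- function(su, pat, mixture, fix_w_plus = NULL) {
  if (.pattern_invariant(su, pat)) {
    all_missing <- all(is.na(su$ld$states[, pat]))
    return(list(alpha = NA_real_, beta_minus = NA_real_,
                beta_plus = NA_real_, weight_plus = NA_real_,
                statistic = 0, p_value = 1,
                classification = if (all_missing) "untestable" else "neutral",
                lnl_alt = NA_real_, lnl_null = NA_real_))
  }
  ldp <- .pattern_ld(su, pat)
  nedge <- nrow(ldp$edge)
  mix_nll <- function(la, ldel, lbp, qw) {
    a <- exp(la); delta <- stats::plogis(ldel); w <- stats::plogis(qw)
    eig <- list(.scaled_eig(su, delta, a),
                .scaled_eig(su, exp(lbp - la), a))
    cw <- matrix(c(rep(1 - w, nedge), rep(w, nedge)), nedge, 2)
    -.prune(ldp, eig, cw)$loglik
  }
  # null: beta+ = alpha
  nll_null <- function(p) mix_nll(p[1], p[2], p[1], p[3])
  lo <- c(.LOG_LOWER, -10, -10); hi <- c(.LOG_UPPER, 10, 10)
  onull <- NULL
  for (st in list(c(0, 0, 0), c(log(0.5), -2, 1))) {
    o <- stats::optim(st, nll_null, method = "L-BFGS-B", lower = lo,
                      upper = hi, control = list(factr = 1e9))
    if (is.null(onull) || o$value < onull$value) onull <- o
  }
  if (!is.null(fix_w_plus)) {
    qw_fix <- stats::qlogis(min(max(fix_w_plus, 1e-9), 1 - 1e-9))
    nll_alt <- function(p) mix_nll(p[1], p[2], p[3], qw_fix)
    lo_a <- c(.LOG_LOWER, -10, .LOG_LOWER); hi_a <- c(.LOG_UPPER, 10, .LOG_UPPER)
    starts <- list(c(onull$par[1], onull$par[2], onull$par[1]),
                   c(onull$par[1], onull$par[2], onull$par[1] + log(5)))
    oalt <- NULL
    for (st in starts) {
      o <- stats::optim(st, nll_alt, method = "L-BFGS-B", lower = lo_a,
                        upper = hi_a, control = list(factr = 1e9))
      if (is.null(oalt) || o$value < oalt$value) oalt <- o
    }
    par <- c(oalt$par[1:3], qw_fix)
  } else {
    nll_alt <- function(p) mix_nll(p[1], p[2], p[3], p[4])
    lo_a <- c(.LOG_LOWER, -10, .LOG_LOWER, -10)
    hi_a <- c(.LOG_UPPER, 10, .LOG_UPPER, 10)
    starts <- list(c(onull$par[1], onull$par[2], onull$par[1], onull$par[3]),
                   c(onull$par[1], onull$par[2], onull$par[1] + log(6),
                     stats::qlogis(0.3)))
    oalt <- NULL
    for (st in starts) {
      o <- stats::optim(st, nll_alt, method = "L-BFGS-B", lower = lo_a,
                        upper = hi_a, control = list(factr = 1e9))
      if (is.null(oalt) || o$value < oalt$value) oalt <- o
    }
    par <- oalt$par
  }
  stat <- max(0, 2 * (onull$value - oalt$value))
  alpha <- exp(par[1]); delta <- stats::plogis(par[2])
  list(alpha = alpha, beta_minus = delta * alpha, beta_plus = exp(par[3]),
       weight_plus = stats::plogis(par[4]), statistic = stat,
       p_value = .chisq_mix_pvalue(stat, 2, mixture),
       lnl_alt = -oalt$value, lnl_null = -onull$value)
}

#' Mixed-effects (MEME-style) test of episodic selection
#'
#' Per site, branches are a two-class mixture: with weight `1 - w+` the
#' nonsynonymous rate is `beta- <= alpha`, and with weight `w+` it is an
#' unconstrained `beta+`.  The null constrains `beta+ = alpha`.  Because a
#' branch draws its class independently, the site likelihood is obtained by
#' pruning with per-branch mixture transition matrices.  The default null
#' reference is the conservative chi-squared with 2 df; a mixture over
#' df 0/1/2 can be supplied instead.
#'
#' @inheritParams fel_site_test
#' @param mixture Optional weights over chi-squared df `0,1,2` for the null
#'   distribution.
#' @param fix_w_plus Fix the mixture weight `w+` (used to recover the
#'   fixed-effects alternative at `w+ = 1`).
#' @return One-row data frame: `site`, `alpha`, `beta_minus`, `beta_plus`,
#'   `weight_plus`, `lrt_statistic`, `p_value`, `classification`.
#' @export
meme_site_test <- function(aln, tree = NULL, site, global_fit,
                           p_threshold = 0.05, mixture = NULL,
                           fix_w_plus = NULL) {
  meme_scan(aln, tree, global_fit, sites = site, p_threshold = p_threshold,
            mixture = mixture, fix_w_plus = fix_w_plus)
}

#' @rdname meme_site_test
#' @param sites Sites to test (default all).
#' @export
meme_scan <- function(aln, tree = NULL, global_fit, sites = NULL,
                      p_threshold = 0.05, mixture = NULL,
                      fix_w_plus = NULL) {
  su <- .site_test_setup(aln, tree, global_fit)
  if (is.null(sites)) sites <- seq_len(aln$n_codons)
  pats <- unique(su$ld$map[sites])
  fits <- lapply(pats, function(p)
    .meme_fit_pattern(su, p, mixture, fix_w_plus))
  idx <- match(su$ld$map[sites], pats)
  out <- do.call(rbind, lapply(seq_along(sites), function(k) {
    f <- fits[[idx[k]]]
    cls <- if (!is.null(f$classification)) f$classification else {
      if (f$p_value <= p_threshold && f$beta_plus > f$alpha &&
          f$weight_plus > 1e-6) "positive" else "neutral"
    }
    data.frame(site = sites[k], alpha = f$alpha, beta_minus = f$beta_minus,
               beta_plus = f$beta_plus, weight_plus = f$weight_plus,
               lrt_statistic = f$statistic, p_value = f$p_value,
               lnl_alt = f$lnl_alt,
               classification = cls, stringsAsFactors = FALSE)
  }))
  class(out) <- c("site_test", "data.frame")
  attr(out, "test") <- "MEME"
  out
}

#' Gene-wide branch-site test of episodic diversifying selection
#'
#' BUSTED-style random-effects test: every branch-site draws its dN/dS
#' ratio independently from a shared three-class distribution with
#' `omega1 <= omega2 <= 1 <= omega3`; the null constrains `omega3 = 1`.
#' Branch lengths (up to one free scale factor), kappa and codon
#' frequencies come from the global fit.  Synonymous-rate site variation is
#' not modelled.  Reports the LRT against a conservative chi-squared(2)
#' reference and per-site evidence ratios (unconstrained / constrained
#' site likelihood at the respective MLEs).
#'
#' @inheritParams fel_site_test
#' @param seed Integer seed for the extra optimizer start.
#' @param n_starts Optimizer starts per model.
#' @return Object of class `busted_result`: `omega`, `weights`, `lnL_alt`,
#'   `lnL_null`, `statistic`, `p_value`, `evidence_ratios` (per site),
#'   `untestable`.
#' @export
busted_gene_test <- function(aln, tree = NULL, global_fit, seed = 1,
                             n_starts = 2) {
  if (length(aln$taxa) < 3L)
    stop("gene-wide test needs at least 3 taxa")
  su <- .site_test_setup(aln, tree, global_fit)
  ld <- su$ld
  if (ncol(ld$states) <= 2L) {
    return(structure(list(untestable = TRUE, omega = NULL, weights = NULL,
                          statistic = NA_real_, p_value = NA_real_,
                          evidence_ratios = rep(NA_real_, aln$n_codons)),
                     class = "busted_result"))
  }
  nedge <- nrow(ld$edge)

  unpack <- function(p, null) {
    om2 <- stats::plogis(p[1])
    om1 <- om2 * stats::plogis(p[2])
    w1 <- stats::plogis(p[3])
    w2 <- (1 - w1) * stats::plogis(p[4])
    om3 <- if (null) 1 else 1 + exp(p[5])
    sc <- exp(p[if (null) 5 else 6])
    list(omega = c(om1, om2, om3), weights = c(w1, w2, 1 - w1 - w2),
         scale = sc)
  }
  nll <- function(p, null) {
    u <- unpack(p, null)
    eig <- lapply(u$omega, function(w) .scaled_eig(su, w, u$scale))
    cw <- matrix(rep(u$weights, each = nedge), nedge, 3)
    -.prune(ld, eig, cw)$loglik
  }
  fit_model <- function(null, extra_starts = list()) {
    npar <- if (null) 5L else 6L
    lo <- c(-15, -15, -15, -15, if (!null) -15, log(0.2))
    hi <- c(15, 15, 15, 15, if (!null) 4, log(5))
    base <- c(stats::qlogis(0.8), stats::qlogis(0.3), stats::qlogis(0.7),
              stats::qlogis(2 / 3), if (!null) log(1), 0)
    starts <- c(list(base), extra_starts)
    set.seed(seed)
    while (length(starts) < n_starts + length(extra_starts))
      starts <- c(starts, list(pmin(pmax(base + stats::rnorm(npar, 0, 1),
                                         lo), hi)))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(stats::optim(st, nll, null = null, method = "L-BFGS-B",
                                 lower = lo, upper = hi,
                                 control = list(factr = 1e8, maxit = 300)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    best
  }
  onull <- fit_model(TRUE)
  # start the alternative from the null optimum (omega3 -> 1) to guarantee
  # the nesting inequality
  null_as_alt <- c(onull$par[1:4], -15, onull$par[5])
  oalt <- fit_model(FALSE, extra_starts = list(null_as_alt))
  stat <- max(0, 2 * (onull$value - oalt$value))
  p <- stats::pchisq(stat, 2, lower.tail = FALSE)

  site_ll <- function(o, null) {
    u <- unpack(o$par, null)
    eig <- lapply(u$omega, function(w) .scaled_eig(su, w, u$scale))
    cw <- matrix(rep(u$weights, each = nedge), nedge, 3)
    .prune(ld, eig, cw)$pattern_loglik[ld$map]
  }
  er <- exp(site_ll(oalt, FALSE) - site_ll(onull, TRUE))
  ua <- unpack(oalt$par, FALSE)
  structure(list(untestable = FALSE, omega = ua$omega, weights = ua$weights,
                 lnL_alt = -oalt$value, lnL_null = -onull$value,
                 statistic = stat, p_value = p, evidence_ratios = er),
            class = "busted_result")
}

#' @export
print.busted_result <- function(x, ...) {
  if (isTRUE(x$untestable)) {
    cat("Gene-wide episodic selection test: untestable (too few site patterns)\n")
    return(invisible(x))
  }
  cat(sprintf("Gene-wide episodic selection test: LRT = %.3f, p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  omega classes: %s\n",
              paste(sprintf("%.3f (w=%.3f)", x$omega, x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Summarize positively selected sites across tests
#'
#' Collates the episodic (MEME-style) and pervasive (FEL-style) site lists
#' for a gene: sites called by each test at the p-value threshold, their
#' intersection (sites under both episodic and pervasive selection), and
#' the episodic sites additionally supported by a gene-wide evidence ratio
#' above the cutoff.
#'
#' @param meme A [meme_scan()] result.
#' @param fel A [fel_scan()] result.
#' @param evidence_ratios Optional per-site evidence ratios from
#'   [busted_gene_test()].
#' @param p_threshold Significance threshold for site calls (default 0.05).
#' @param er_threshold Evidence-ratio cutoff (default 2).
#' @return Object of class `selection_summary`: `meme_sites`, `fel_sites`,
#'   `both`, `meme_er_supported`, plus the thresholds.
#' @export
summarize_selected_sites <- function(meme = NULL, fel = NULL,
                                     evidence_ratios = NULL,
                                     p_threshold = 0.05, er_threshold = 2) {
  pick <- function(df, pos_col) {
    if (is.null(df) || nrow(df) == 0) return(integer(0))
    ok <- df$p_value <= p_threshold & !is.na(df[[pos_col[1]]]) &
      df[[pos_col[1]]] > df[[pos_col[2]]]
    sort(df$site[ok & df$classification != "untestable"])
  }
  meme_sites <- pick(meme, c("beta_plus", "alpha"))
  fel_sites <- pick(fel, c("beta", "alpha"))
  er_sites <- integer(0)
  if (!is.null(evidence_ratios) && length(meme_sites))
    er_sites <- meme_sites[evidence_ratios[meme_sites] > er_threshold]
  structure(list(meme_sites = meme_sites, fel_sites = fel_sites,
                 both = intersect(meme_sites, fel_sites),
                 meme_er_supported = er_sites,
                 p_threshold = p_threshold, er_threshold = er_threshold),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat("Sites under positive selection (p <=", x$p_threshold, "):\n")
  cat("  episodic (MEME-style): ", fmt(x$meme_sites), "\n")
  cat("  pervasive (FEL-style): ", fmt(x$fel_sites), "\n")
  cat("  both:                  ", fmt(x$both), "\n")
  cat("  episodic with ER >", x$er_threshold, ":", fmt(x$meme_er_supported), "\n")
  invisible(x)
}

#' Write per-site test results as TSV
#'
#' @param x A [fel_scan()]/[meme_scan()] data frame.
#' @param path Output path.
#' @export
write_site_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
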