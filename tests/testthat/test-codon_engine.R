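test_that("the GY94 rate matrix has the defining structural properties", {
  code <- standard_genetic_code()
  for (par in list(c(1, 1), c(2, 0.3), c(5, 2.5))) {
    Q <- gy94_rate_matrix(par[1], par[2])
    pi <- attr(Q, "pi")
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    expect_lt(abs(-sum(pi * diag(Q)) - 1), 1e-10)
    # reversibility: pi_i q_ij = pi_j q_ji
    F <- pi * Q
    expect_lt(max(abs(F - t(F))), 1e-12)
  }
  # multi-position changes are forbidden
  Q <- gy94_rate_matrix(2, 0.5)
  expect_identical(Q["ATG", "CCC"], 0)
  expect_identical(Q["AAA", "TTT"], 0)
  # omega = kappa = 1, equal pi: all allowed changes share one rate
  Q1 <- gy94_rate_matrix(1, 1)
  off <- Q1[row(Q1) != col(Q1)]
  expect_lt(diff(range(off[off > 0])), 1e-15)
})

test_that("frequency-weighted rate matrices keep detailed balance", {
  fx <- fixture_alignment(n_taxa = 5, n_codons = 30, seed = 3)
  for (fm in c("F1x4", "F3x4")) {
    pi <- ohnosel:::.codon_frequencies(fx$aln, fm)
    Q <- gy94_rate_matrix(2, 0.4, pi)
    F <- pi * Q
    expect_lt(max(abs(F - t(F))), 1e-12)
    expect_lt(abs(sum(pi) - 1), 1e-12)
  }
})

test_that("transition probabilities behave as a stochastic semigroup", {
  Q <- gy94_rate_matrix(2, 0.3)
  pi <- attr(Q, "pi")
  expect_equal(transition_probs(Q, 0), diag(61), ignore_attr = TRUE,
               tolerance = 1e-12)
  P1 <- transition_probs(Q, 0.37)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  expect_lt(max(abs(P1 %*% P1 - transition_probs(Q, 0.74))), 1e-8)
  # ergodic limit: rows converge to the stationary distribution
  Pbig <- transition_probs(Q, 200)
  expect_lt(max(abs(sweep(Pbig, 2, pi))), 1e-10)
  expect_error(transition_probs(Q, -1), "non-negative")
})

test_that("pruning log-likelihood matches closed forms on degenerate trees", {
  code <- standard_genetic_code()
  # two identical sequences joined by total branch length zero
  seqs <- c(A = "ATGTTTGGG", B = "ATGTTTGGG")
  aln <- codon_alignment(seqs)
  tr <- read_newick("(A:0,B:0);")
  n <- 61
  expect_equal(log_likelihood(aln, tr, kappa = 2, omega = 0.5),
               3 * log(1 / n), tolerance = 1e-9, ignore_attr = TRUE)
  # single effective branch: lnL = sum log(pi) + log P(codon_a -> codon_b)
  aln2 <- codon_alignment(c(A = "ATG", B = "ATA"))
  tr2 <- read_newick("(A:0,B:0.2);")
  Q <- gy94_rate_matrix(2, 0.5)
  P <- transition_probs(Q, 0.2)
  expect_equal(as.numeric(log_likelihood(aln2, tr2, kappa = 2, omega = 0.5)),
               log(1 / n) + log(P["ATG", "ATA"]), tolerance = 1e-9)
})

test_that("pruning equals exhaustive ancestral-state enumeration", {
  for (seed in 1:3) {
    fx <- fixture_alignment(n_taxa = 3, n_codons = 2, seed = seed)
    expect_equal(as.numeric(log_likelihood(fx$aln, fx$tree, fx$kappa, fx$omega)),
                 enum_loglik(fx$aln, fx$tree, fx$kappa, fx$omega),
                 tolerance = 1e-8)
  }
  fx <- fixture_alignment(n_taxa = 4, n_codons = 2, seed = 9)
  expect_equal(as.numeric(log_likelihood(fx$aln, fx$tree, fx$kappa, fx$omega)),
               enum_loglik(fx$aln, fx$tree, fx$kappa, fx$omega),
               tolerance = 1e-8)
  # with a missing codon
  fx$aln$codons[1, 1] <- "---"
  expect_equal(as.numeric(log_likelihood(fx$aln, fx$tree, fx$kappa, fx$omega)),
               enum_loglik(fx$aln, fx$tree, fx$kappa, fx$omega),
               tolerance = 1e-8)
})

test_that("model fits are deterministic, maximizing, and nested", {
  fx <- fixture_alignment(n_taxa = 6, n_codons = 60, seed = 21, omega = 0.3)
  tree <- flag_foreground_clade(fx$tree, fx$tree$tip.label[1], include_clade = FALSE)
  m0a <- codon_fit(fx$aln, tree, model = "M0", freq_model = "equal",
                   optimize_branch_lengths = FALSE, n_starts = 2, seed = 7)
  m0b <- codon_fit(fx$aln, tree, model = "M0", freq_model = "equal",
                   optimize_branch_lengths = FALSE, n_starts = 2, seed = 7)
  expect_identical(m0a$omega, m0b$omega)   # bit-identical under one seed
  expect_identical(m0a$lnL, m0b$lnL)
  # fitted lnL is at least the likelihood at the generating parameters
  ll_truth <- log_likelihood(fx$aln, fx$tree, kappa = fx$kappa,
                             omega = fx$omega)
  expect_gte(m0a$lnL, as.numeric(ll_truth) - 1e-6)
  m2 <- codon_fit(fx$aln, tree, model = "two-ratio", freq_model = "equal",
                  optimize_branch_lengths = FALSE, n_starts = 1, seed = 7)
  expect_gte(m2$lnL, m0a$lnL - 1e-6)
  expect_named(m2$omega, c("omega0", "omega1"))
  expect_s3_class(summary(m0a), "summary.codon_fit")
  expect_identical(unname(coef(m0a)["kappa"]), m0a$kappa)
  expect_identical(attr(logLik(m0a), "df"), m0a$np)
})

test_that("two-ratio configuration errors are caught", {
  fx <- fixture_alignment(n_taxa = 4, n_codons = 10, seed = 5)
  expect_error(codon_fit(fx$aln, fx$tree, model = "two-ratio"),
               "no foreground")
  tree <- fx$tree
  tree$foreground <- rep(TRUE, nrow(tree$edge))
  expect_error(codon_fit(fx$aln, tree, model = "two-ratio"),
               "all branches foreground")
})

test_that("a foreground restricted to zero-length branches is flagged unidentifiable", {
  fx <- fixture_alignment(n_taxa = 5, n_codons = 30, seed = 13)
  tree <- fx$tree
  tip <- 2L
  e <- which(tree$edge[, 2] == tip)
  tree$edge.length[e] <- 0
  tree$foreground <- seq_len(nrow(tree$edge)) == e
  fit <- suppressWarnings(
    codon_fit(fx$aln, tree, model = "two-ratio", freq_model = "equal",
              optimize_branch_lengths = FALSE, n_starts = 1, seed = 1))
  # fast mode keeps the zero length fixed: omega1 has no data
  expect_false(fit$converged)
  expect_match(fit$notes, "not identifiable")
})

test_that("likelihood-ratio tests follow the chi-squared reference", {
  a <- list(lnL = -100, np = 4)
  b <- list(lnL = -100, np = 5)
  lrt <- likelihood_ratio_test(a, b)
  expect_identical(lrt$statistic, 0)
  expect_identical(lrt$p_value, 1)
  b$lnL <- -100 + 3.841 / 2
  expect_equal(likelihood_ratio_test(a, b, df = 1)$p_value, 0.05,
               tolerance = 1e-3)
  # monotone: larger statistic, smaller p
  b2 <- list(lnL = -95, np = 5)
  expect_lt(likelihood_ratio_test(a, b2, df = 1)$p_value,
            likelihood_ratio_test(a, b, df = 1)$p_value)
  b$lnL <- -101
  expect_error(likelihood_ratio_test(a, b), "nesting error")
  # chi-squared mixtures: df-0 mass turns into a point mass at p = 1
  expect_equal(ohnosel:::.chisq_mix_pvalue(0, 2, c(0.5, 0.5)), 1)
  expect_equal(ohnosel:::.chisq_mix_pvalue(3.2, 2, c(0.5, 0.5)),
               0.5 * pchisq(3.2, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("branch_model_test tabulates both models and writes a report", {
  fx <- fixture_alignment(n_taxa = 6, n_codons = 40, seed = 31)
  bt <- branch_model_test(fx$aln, fx$tree, foreground = fx$tree$tip.label[1:2],
                          freq_model = "equal",
                          optimize_branch_lengths = FALSE, n_starts = 1,
                          seed = 2)
  expect_s3_class(bt, "branch_test")
  expect_identical(nrow(bt$table), 2L)
  expect_true(is.finite(bt$lrt$p_value))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fit_report(bt, f)
  expect_identical(nrow(utils::read.delim(f)), 2L)
})
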