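# small global fit shared by the site-test unit checks
.small_fit <- function(aln, tree, seed = 1) {
  codon_fit(aln, tree, model = "M0", freq_model = "equal",
            optimize_branch_lengths = FALSE, n_starts = 1, seed = seed)
}

test_that("ancestor counting matches closed-form expectations on tiny trees", {
  # two leaves differing by one synonymous change
  aln <- codon_alignment(c(A = "ATGATT", B = "ATGATC"))
  tr <- read_newick("(A:0.1,B:0.1);")
  fit <- .small_fit(aln, tr)
  sl <- slac_site_counts(aln, global_fit = fit, tree = tr)
  expect_identical(sl$obs_syn[1] + sl$obs_nonsyn[1], 0)   # invariant ATG
  expect_identical(sl$p_positive[1], 1)
  expect_equal(sl$obs_syn[2], 1)                          # ATT vs ATC
  expect_equal(sl$obs_nonsyn[2], 0)
  # identical columns: no change, p = 1
  expect_identical(sl$p_negative[1], 1)
})

test_that("ancestor counting equals the exhaustive reconstruction+path oracle", {
  for (seed in c(2, 4, 6)) {
    fx <- fixture_alignment(n_taxa = 4, n_codons = 3, seed = seed,
                            omega = 0.8)
    fit <- .small_fit(fx$aln, fx$tree)
    sl <- slac_site_counts(fx$aln, global_fit = fit, tree = fx$tree)
    anc <- enum_ancestral(fx$aln, fx$tree, fit$kappa, unname(fit$omega),
                          fit$pi)
    code <- standard_genetic_code()
    idx <- match(fx$aln$codons, code$sense_codons)
    dim(idx) <- dim(fx$aln$codons)
    idx <- idx[match(fx$tree$tip.label, fx$aln$taxa), , drop = FALSE]
    n_tip <- 4L
    for (s in seq_len(fx$aln$n_codons)) {
      syn <- 0; nonsyn <- 0
      skip_site <- FALSE
      for (e in seq_len(nrow(fx$tree$edge))) {
        pa <- fx$tree$edge[e, 1]; ch <- fx$tree$edge[e, 2]
        ps <- anc[as.character(pa), s]
        cs <- if (ch <= n_tip) idx[ch, s] else anc[as.character(ch), s]
        if (is.na(ps) || is.na(cs) || ps == cs) next
        pc <- oracle_path_counts(ps, cs)
        if (is.null(pc)) { skip_site <- TRUE; break }
        syn <- syn + pc["syn"]; nonsyn <- nonsyn + pc["nonsyn"]
      }
      if (skip_site) next  # no stop-free shortest path: fallback differs
      expect_equal(sl$obs_syn[s], unname(syn), tolerance = 1e-9,
                   label = sprintf("seed %d site %d syn", seed, s))
      expect_equal(sl$obs_nonsyn[s], unname(nonsyn), tolerance = 1e-9,
                   label = sprintf("seed %d site %d nonsyn", seed, s))
    }
  }
})

test_that("marginal ancestral reconstruction agrees with enumeration", {
  fx <- fixture_alignment(n_taxa = 4, n_codons = 3, seed = 11)
  fit <- .small_fit(fx$aln, fx$tree)
  anc_pkg <- ancestral_reconstruction(fx$aln, fx$tree, fit)
  anc_or <- enum_ancestral(fx$aln, fx$tree, fit$kappa, unname(fit$omega),
                           fit$pi)
  expect_identical(anc_pkg[rownames(anc_or), ], anc_or)
})

test_that("site tests return p = 1 and neutral classification at invariant sites", {
  aln <- codon_alignment(c(A = "ATGATG", B = "ATGATG", C = "ATGATG"))
  tr <- read_newick("((A:0.1,B:0.1):0.05,C:0.1);")
  fit <- .small_fit(aln, tr)
  fel <- fel_site_test(aln, site = 1, global_fit = fit)
  expect_identical(fel$p_value, 1)
  expect_identical(fel$lrt_statistic, 0)
  expect_identical(fel$classification, "neutral")
  meme <- meme_site_test(aln, site = 1, global_fit = fit)
  expect_identical(meme$p_value, 1)
  expect_identical(meme$classification, "neutral")
})

test_that("forcing the mixture weight to one reproduces the fixed-effects alternative", {
  fx <- fixture_alignment(n_taxa = 8, n_codons = 6, seed = 17, omega = 0.6)
  fit <- .small_fit(fx$aln, fx$tree)
  fel <- fel_scan(fx$aln, global_fit = fit, sites = 1:4)
  memefix <- meme_scan(fx$aln, global_fit = fit, sites = 1:4, fix_w_plus = 1)
  keep <- !is.na(fel$lnl_alt)
  expect_true(any(keep))
  expect_equal(memefix$lnl_alt[keep], fel$lnl_alt[keep], tolerance = 1e-6)
})

test_that("site-test nesting holds: alternative lnL never below the null", {
  fx <- fixture_alignment(n_taxa = 8, n_codons = 10, seed = 23, omega = 0.4)
  fit <- .small_fit(fx$aln, fx$tree)
  fel <- fel_scan(fx$aln, global_fit = fit)
  meme <- meme_scan(fx$aln, global_fit = fit)
  expect_true(all(fel$lrt_statistic >= 0))
  expect_true(all(meme$lrt_statistic >= 0))
  expect_true(all(fel$p_value >= 0 & fel$p_value <= 1))
  expect_true(all(meme$p_value >= 0 & meme$p_value <= 1))
  # MEME's beta-minus respects its constraint
  ok <- !is.na(meme$beta_minus)
  expect_true(all(meme$beta_minus[ok] <= meme$alpha[ok] + 1e-8))
})

test_that("the gene-wide test flags degenerate alignments and orders omega classes", {
  aln <- codon_alignment(c(A = "ATGATG", B = "ATGATG", C = "ATGATG"))
  tr <- read_newick("((A:0.1,B:0.1):0.05,C:0.1);")
  fit <- .small_fit(aln, tr)
  bus <- busted_gene_test(aln, global_fit = fit)
  expect_true(bus$untestable)

  fx <- fixture_alignment(n_taxa = 8, n_codons = 40, seed = 29, omega = 0.3)
  fit2 <- .small_fit(fx$aln, fx$tree)
  bus2 <- busted_gene_test(fx$aln, global_fit = fit2, seed = 1)
  expect_false(bus2$untestable)
  expect_true(bus2$omega[1] <= bus2$omega[2] + 1e-8)
  expect_true(bus2$omega[2] <= 1 + 1e-8)
  expect_gte(bus2$omega[3], 1 - 1e-8)
  expect_equal(sum(bus2$weights), 1, tolerance = 1e-8)
  expect_gte(bus2$statistic, 0)
  expect_length(bus2$evidence_ratios, fx$aln$n_codons)
  expect_true(all(bus2$evidence_ratios >= 0))
})

test_that("evidence ratios carry no signal at conserved sites", {
  fx <- fixture_alignment(n_taxa = 10, n_codons = 60, seed = 37, omega = 0.2)
  fit <- .small_fit(fx$aln, fx$tree)
  bus <- busted_gene_test(fx$aln, global_fit = fit, seed = 1)
  invariant <- which(apply(fx$aln$codons, 2,
                           function(x) length(unique(x)) == 1))
  expect_true(length(invariant) > 0)
  expect_true(all(bus$evidence_ratios[invariant] >= 0.5 &
                    bus$evidence_ratios[invariant] <= 2))
})

test_that("site summaries apply set logic and evidence-ratio thresholds", {
  meme <- data.frame(site = c(3, 7, 9), p_value = c(0.01, 0.02, 0.5),
                     beta_plus = c(5, 4, 2), alpha = c(1, 1, 1),
                     classification = "positive")
  fel <- data.frame(site = c(7, 9), p_value = c(0.03, 0.2),
                    beta = c(3, 0.1), alpha = c(1, 1),
                    classification = c("positive", "neutral"))
  er <- rep(1, 10); er[3] <- 2.1; er[7] <- 9
  s <- summarize_selected_sites(meme, fel, evidence_ratios = er)
  expect_identical(s$meme_sites, c(3, 7))
  expect_identical(s$fel_sites, 7)
  expect_identical(s$both, 7)
  expect_identical(s$meme_er_supported, c(3, 7))
  # ER threshold counting
  s2 <- summarize_selected_sites(meme, fel,
                                 evidence_ratios = replace(er, c(3, 7), c(1.5, 9)))
  expect_identical(s2$meme_er_supported, 7)
  # empty inputs give an empty report, not an error
  s3 <- summarize_selected_sites(NULL, NULL)
  expect_length(s3$meme_sites, 0)
  expect_length(s3$both, 0)
})
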