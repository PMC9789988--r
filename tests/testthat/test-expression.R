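test_that("RPKM follows its defining formula and proportionality", {
  expect_identical(rpkm(10, 2, 1e6), 5)
  expect_identical(rpkm(0, 2, 1e6), 0)
  expect_equal(rpkm(10, 2, 2e6), rpkm(10, 2, 1e6) / 2)
  expect_error(rpkm(1, 0, 1e6), "value error")
  expect_error(rpkm(1, 2, 0), "value error")
})

test_that("TPM normalizes to one million and is scale invariant", {
  expect_equal(tpm_from_rpkm(c(2, 3, 5)), c(2e5, 3e5, 5e5))
  set.seed(3)
  v <- rexp(50)
  expect_equal(sum(tpm_from_rpkm(v)), 1e6, tolerance = 1e-9)
  expect_equal(tpm_from_rpkm(7 * v), tpm_from_rpkm(v), tolerance = 1e-12)
  expect_error(tpm_from_rpkm(c(0, 0)), "value error")
})

test_that("per-tissue TPM tables sum to one million over the transcriptome", {
  sim <- simulate_expression(expression_scenario(
    species = "sp1",
    mean_matrix = matrix(c(50, 80), 1, 2,
                         dimnames = list("P1", c("gill", "heart"))),
    seed = 5))
  tab <- tpm_table(sim$counts, sim$lengths)
  expect_true(all(abs(colSums(tab) - 1e6) < 1e-3))
})

test_that("median heatmaps take medians over possessing species only", {
  t1 <- matrix(c(1, 10), 1, 2, dimnames = list("g1", c("gill", "heart")))
  t2 <- matrix(c(2, 20), 1, 2, dimnames = list("g2", c("gill", "heart")))
  t3 <- matrix(c(100, 30), 1, 2, dimnames = list("g3", c("gill", "heart")))
  pmap <- data.frame(species = c("s1", "s2", "s3"),
                     gene = c("g1", "g2", "g3"),
                     paralog = c("P", "P", "P"))
  hm <- median_heatmap(list(s1 = t1, s2 = t2, s3 = t3), pmap)
  expect_identical(hm["P", "gill"], 2)
  expect_identical(hm["P", "heart"], 20)
  # single species: the matrix is that species' values
  hm1 <- median_heatmap(list(s1 = t1), pmap[1, ])
  expect_identical(hm1["P", "heart"], 10)
  # species order must not matter
  hm_perm <- median_heatmap(list(s3 = t3, s1 = t1, s2 = t2), pmap)
  expect_identical(hm, hm_perm)
  # a paralog absent everywhere in a tissue is missing, not zero
  pmap2 <- rbind(pmap, data.frame(species = "s9", gene = "g9", paralog = "Q"))
  hm2 <- median_heatmap(list(s1 = t1), pmap2)
  expect_true(is.na(hm2["Q", "gill"]))
})

test_that("expression simulation is seeded and approaches Poisson at infinite dispersion", {
  sc <- expression_scenario(species = c("s1", "s2"),
                            mean_matrix = matrix(c(40, 60, 20, 10), 2, 2,
                                                 dimnames = list(c("A", "B"),
                                                                 c("gill", "heart"))),
                            seed = 7)
  a <- simulate_expression(sc)
  b <- simulate_expression(sc)
  expect_identical(a$counts, b$counts)
  # Poisson limit: sample variance tracks the mean
  scp <- expression_scenario(species = "s", n_background = 0,
                             mean_matrix = matrix(100, 1, 600,
                                                  dimnames = list("A", paste0("t", 1:600))),
                             dispersion = Inf, seed = 11)
  cnt <- simulate_expression(scp)$counts$count
  expect_lt(abs(var(cnt) / mean(cnt) - 1), 0.25)
  # finite dispersion is overdispersed
  scn <- expression_scenario(species = "s", n_background = 0,
                             mean_matrix = matrix(100, 1, 600,
                                                  dimnames = list("A", paste0("t", 1:600))),
                             dispersion = 2, seed = 11)
  cntn <- simulate_expression(scn)$counts$count
  expect_gt(var(cntn) / mean(cntn), 5)
})

test_that("a gill-elevated paralog dominates its row of the median heatmap", {
  mm <- matrix(c(30, 40, 35, 25,
                 15, 300, 20, 10), 2, 4, byrow = TRUE,
               dimnames = list(c("HIF1Aa", "HIF2Aa"),
                               c("brain", "gill", "heart", "liver")))
  sim <- simulate_expression(expression_scenario(
    species = paste0("sp", 1:5), mean_matrix = mm, seed = 13))
  tpms <- lapply(split(sim$counts, sim$counts$species),
                 function(d) tpm_table(d, sim$lengths))
  hm <- median_heatmap(tpms, sim$paralog_map)
  expect_identical(names(which.max(hm["HIF2Aa", ])), "gill")
})
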