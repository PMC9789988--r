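nb <- function(species, focal, up, down, ...) {
  gene_neighborhood(species, focal, c(-(seq_along(up)), seq_along(down)),
                    c(up, down), ...)
}

test_that("shared flank counts follow the set semantics", {
  u <- paste0("U", 1:10); d <- paste0("D", 1:10)
  n1 <- nb("sp1", "G", u, d)
  n2 <- nb("sp2", "G", u, d)
  expect_identical(shared_flank_count(n1, n2), 20L)
  n3 <- nb("sp3", "G", paste0("X", 1:10), paste0("Y", 1:10))
  expect_identical(shared_flank_count(n1, n3), 0L)
  # unknowns never match; duplicates count once; symmetric
  n4 <- nb("sp4", "G", c("U1", "U1", "unknown", paste0("Z", 1:7)),
           c("unknown", paste0("W", 1:9)))
  expect_identical(shared_flank_count(n1, n4), 1L)
  expect_identical(shared_flank_count(n4, n1), 1L)
  # self-comparison returns the number of distinct known symbols
  expect_identical(shared_flank_count(n4, n4), 17L)
  # bounded by the smaller neighborhood's distinct known symbols
  expect_lte(shared_flank_count(n1, n4),
             min(length(unique(n1$symbols)), 17L))
})

test_that("conserved runs walk outward and break on mismatch or unknown", {
  u <- paste0("U", 1:10); d <- paste0("D", 1:10)
  n1 <- nb("a", "G", u, d)
  expect_identical(as.integer(conserved_run(n1, nb("b", "G", u, d), "up")), 10L)
  u2 <- u; u2[1] <- "OTHER"
  expect_identical(as.integer(conserved_run(n1, nb("b", "G", u2, d), "up")), 0L)
  u3 <- u; u3[4] <- "unknown"
  expect_identical(as.integer(conserved_run(n1, nb("b", "G", u3, d), "up")), 3L)
  d2 <- d; d2[6] <- "ZZ"
  expect_identical(as.integer(conserved_run(n1, nb("b", "G", u, d2), "down")), 5L)
})

test_that("duplication labels follow the ancestral- and sister-sharing rules", {
  anc <- nb("gar", "G", paste0("U", 1:10), paste0("D", 1:10))
  p1 <- nb("fish", "Ga", c(paste0("U", 1:8), "N1", "N2"),
           c("N3", paste0("D", 2:10)))
  p2 <- nb("fish", "Gb", c(paste0("U", 1:3), paste0("M", 1:7)),
           paste0("K", 1:10))
  a <- assign_tgd_labels(p1, p2, anc)
  expect_identical(a$labels, c("a", "b"))
  expect_gt(a$scores[1], a$scores[2])
  # ties are unresolved, with scores reported
  tie <- assign_tgd_labels(p1, p1, anc)
  expect_identical(tie$labels, c("unresolved", "unresolved"))
  # single-survivor families stay unsuffixed
  solo <- assign_tgd_labels(p1, p2, anc, retained_in_any_lineage_both = FALSE)
  expect_identical(solo$labels, c("unsuffixed", "unsuffixed"))
  expect_error(assign_tgd_labels(p1, p2, NULL), "configuration error")
  # salmonid duplicates against the sister group
  s <- assign_sgd_labels(p1, p2, anc)
  expect_identical(s$labels, c("s1", "s2"))
  expect_error(assign_sgd_labels(p1, p2, NULL), "configuration error")
})

test_that("neighborhood TSV round-trips preserve content", {
  n1 <- nb("sp1", "G1", paste0("U", 1:10), paste0("D", 1:10))
  n2 <- nb("sp2", "G2", paste0("X", 1:4), paste0("Y", 1:3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_neighborhoods(list(n1, n2), f)
  back <- read_neighborhoods(f)
  expect_length(back, 2)
  expect_identical(back[["sp1:G1"]]$symbols, n1$symbols)
  expect_identical(back[["sp2:G2"]]$offsets, n2$offsets)
})

test_that("simulated WGD neighborhoods match the analytic loss expectation", {
  p_loss <- 0.3
  shared <- vapply(1:400, function(r) {
    sim <- simulate_neighborhoods(neighborhood_scenario(
      loss_prob = p_loss, inversion_prob = 0, seed = r))
    shared_flank_count(sim$copy1, sim$ancestor)
  }, numeric(1))
  expected <- 20 * (1 - p_loss)
  se <- sqrt(20 * p_loss * (1 - p_loss)) / sqrt(400)
  expect_lt(abs(mean(shared) - expected), 3 * se)
  # degenerate rates
  s0 <- simulate_neighborhoods(neighborhood_scenario(loss_prob = 0,
                                                     inversion_prob = 0, seed = 1))
  expect_identical(shared_flank_count(s0$copy1, s0$ancestor), 20L)
  s1 <- simulate_neighborhoods(neighborhood_scenario(loss_prob = 1,
                                                     inversion_prob = 0, seed = 1))
  expect_identical(shared_flank_count(s1$copy1, s1$ancestor), 0L)
  # determinism
  a <- simulate_neighborhoods(neighborhood_scenario(loss_prob = 0.4, seed = 9))
  b <- simulate_neighborhoods(neighborhood_scenario(loss_prob = 0.4, seed = 9))
  expect_identical(a$copy1$symbols, b$copy1$symbols)
})

test_that("asymmetric post-WGD loss drives the s1/s2 labels to the truth", {
  hits <- vapply(1:200, function(r) {
    sim <- simulate_neighborhoods(neighborhood_scenario(
      loss_prob = c(0.15, 0.55), ref_loss_prob = 0.1, seed = 5000 + r))
    lab <- assign_sgd_labels(sim$copy1, sim$copy2, sim$reference)
    identical(lab$labels[1], "s1")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
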