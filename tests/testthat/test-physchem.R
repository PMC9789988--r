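test_that("the z-scale table is complete and the encoding is dimensioned correctly", {
  z <- z_scales()
  expect_identical(dim(z), c(20L, 5L))
  expect_setequal(rownames(z), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  msa <- rbind(a = c("M", "K", "L"), b = c("M", "K", "L"),
               c = c("M", "R", "L"), d = c("M", "K", "V"))
  zm <- encode_zmatrix(msa, sites = 1:3)
  expect_identical(dim(zm), c(4L, 15L))
  # identical sequences give identical rows
  expect_identical(zm["a", ], zm["b", ])
  # one substitution changes exactly the 5 entries of that site
  expect_identical(sum(zm["a", ] != zm["c", ]), 5L)
  expect_equal(which(zm["a", ] != zm["d", ]), 11:15, ignore_attr = TRUE)
  expect_error(encode_zmatrix(msa, sites = 9), "index error")
})

test_that("gap policies impute, zero, or refuse", {
  msa <- rbind(a = c("M", "K"), b = c("M", "-"), c = c("M", "R"))
  z <- z_scales()
  zm <- encode_zmatrix(msa, sites = 1:2)
  expect_equal(unname(zm["b", 6:10]),
               unname(colMeans(z[c("K", "R"), ])))
  expect_true(attr(zm, "missing_mask")["b", 2])
  zm0 <- encode_zmatrix(msa, sites = 1:2, gap_policy = "zero")
  expect_identical(unname(zm0["b", 6:10]), rep(0, 5))
  expect_error(encode_zmatrix(msa, sites = 1:2, gap_policy = "error"), "gap")
  # unknown residues are treated as gaps
  msa2 <- rbind(a = c("M", "X"), b = c("M", "K"), c = c("M", "K"))
  zmx <- encode_zmatrix(msa2, sites = 1:2)
  expect_equal(unname(zmx["a", 6:10]), unname(z["K", ]))
})

test_that("PCA with all components reconstructs the scaled matrix", {
  set.seed(5)
  x <- matrix(rnorm(30 * 8), 30, 8)
  pc <- ohnosel:::.pca_scores(x, min_variance = 1)
  rec <- pc$scores %*% t(pc$rotation[, seq_len(pc$n_pcs)])
  expect_lt(max(abs(rec - pc$centered)), 1e-8)
})

test_that("k-means/BIC selection recovers well-separated blob counts", {
  set.seed(803)
  mu <- matrix(rnorm(3 * 30, 0, 3), 3, 30)
  blobs <- do.call(rbind, lapply(1:3, function(g)
    mu[rep(g, 40), ] + rnorm(40 * 30, 0, 0.3)))
  sel <- select_k(blobs, k_max = 6, seed = 2)
  expect_identical(sel$k, 3L)
  expect_length(sel$bic, 6L)
  # the chosen clustering matches the generating blobs one-to-one
  tab <- table(sel$cluster, rep(1:3, each = 40))
  expect_true(all(rowSums(tab > 0) == 1))
  # determinism: same seed, identical assignments
  sel2 <- select_k(blobs, k_max = 6, seed = 2)
  expect_identical(sel$cluster, sel2$cluster)
  expect_error(select_k(blobs[1:2, ], k_max = 2), "untestable")
})

test_that("a single Gaussian cloud selects one cluster", {
  set.seed(705)
  one <- matrix(rnorm(40 * 40), 40, 40)
  sel <- select_k(one, k_max = 5, seed = 3)
  expect_identical(sel$k, 1L)
})

test_that("DAPC separates separable groups and degrades to chance on shuffled labels", {
  set.seed(17)
  x <- rbind(matrix(rnorm(15 * 10, 0, 0.5), 15, 10),
             matrix(rnorm(15 * 10, 6, 0.5), 15, 10))
  g <- rep(c("g1", "g2"), each = 15)
  fit <- dapc(x, g)
  expect_identical(fit$accuracy, 1)
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-8))
  expect_lte(fit$n_pcs, nrow(x) - 2)
  # permutation null: accuracy near 1/groups
  set.seed(19)
  accs <- vapply(1:10, function(i) dapc(x, sample(g))$accuracy, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
  expect_error(dapc(x, g, n_pcs = 0), "n_pcs")
  expect_error(dapc(x, rep("g1", 30)), "at least 2 groups")
})
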