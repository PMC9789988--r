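#' Five z-scale physicochemical descriptors of the amino acids
#'
#' The extended principal-property ("z-scale") descriptors of Sandberg et
#' al. (1998, J. Med. Chem. 41:2481-2491), transcribed from Table 2 of that
#' reference: z1 tracks hydrophobicity, z2 steric bulk/polarizability, z3
#' polarity, and z4/z5 electronic effects.  Dimensionless.
#'
#' @return A 20 x 5 numeric matrix, rows named by one-letter amino-acid
#'   code, columns `z1`..`z5`.
#' @export
z_scales <- function() {
  txt <- "
A  0.24 -2.32  0.60 -0.14  1.30
R  3.52  2.50 -3.50  1.99 -0.17
N  3.05  1.62  1.04 -1.15  1.61
D  3.98  0.93  1.93 -2.46  0.75
C  0.84 -1.67  3.71  0.18 -2.65
Q  1.75  0.50 -1.44 -1.34  0.66
E  3.11  0.26 -0.11 -3.04 -0.25
G  2.05 -4.06  0.36 -0.82 -0.38
H  2.47  1.95  0.26  3.90  0.09
I -3.89 -1.73 -1.71 -0.84  0.26
L -4.28 -1.30 -1.49 -0.72  0.84
K  2.29  0.89 -2.49  1.49  0.31
M -2.85 -0.22  0.47  1.94 -0.98
F -4.22  1.94  1.06  0.54 -0.62
P -1.66  0.27  1.84  0.70  2.00
S  2.39 -1.07  1.15 -1.39  0.67
T  0.75 -2.18 -1.12 -1.46 -0.40
W -4.36  3.94  0.59  3.44 -1.59
Y -2.54  2.44  0.43  0.04 -1.47
V -2.59 -2.64 -1.54 -0.85 -0.02"
  d <- utils::read.table(text = txt, stringsAsFactors = FALSE)
  out <- as.matrix(d[, -1])
  dimnames(out) <- list(d[[1]], paste0("z", 1:5))
  out
}

#' Encode selected alignment sites as a z-descriptor matrix
#'
#' Builds the "X-matrix" used for physicochemical profiling: one row per
#' taxon and five z-descriptor values per selected site.  Gaps and unknown
#' residues (X) are handled by `gap_policy`; the default imputes the column
#' mean over the non-missing taxa and records a mask.
#'
#' @param msa Protein alignment: a character matrix (taxa x residues, from
#'   [translate_alignment()]) or a [codon_alignment()] (translated
#'   internally).
#' @param sites 1-based alignment columns (e.g. positively selected sites).
#' @param table Descriptor table, default [z_scales()].
#' @param gap_policy `"impute_mean"` (default), `"zero"`, or `"error"`.
#' @return Numeric matrix (taxa x `5 * length(sites)`), class `z_matrix`,
#'   with attributes `sites` and `missing_mask` (taxa x sites logical).
#' @export
encode_zmatrix <- function(msa, sites, table = z_scales(),
                           gap_policy = c("impute_mean", "zero", "error")) {
  gap_policy <- match.arg(gap_policy)
  if (inherits(msa, "codon_alignment")) msa <- translate_alignment(msa)
  if (any(sites < 1 | sites > ncol(msa)))
    stop("index error: site outside alignment (1..", ncol(msa), ")")
  n <- nrow(msa)
  cols <- colnames(table)
  out <- matrix(NA_real_, n, 5L * length(sites),
                dimnames = list(rownames(msa), paste(
                  rep(paste0("site", sites), each = 5), cols, sep = "_")))
  mask <- matrix(FALSE, n, length(sites),
                 dimnames = list(rownames(msa), sites))
  for (k in seq_along(sites)) {
    aa <- toupper(msa[, sites[k]])
    z <- table[match(aa, rownames(table)), , drop = FALSE]
    miss <- is.na(z[, 1])
    mask[, k] <- miss
    if (any(miss)) {
      if (gap_policy == "error")
        stop("gap/unknown residue at site ", sites[k])
      fill <- if (gap_policy == "zero") rep(0, 5) else
        colMeans(z[!miss, , drop = FALSE])
      if (all(miss)) fill <- rep(0, 5)
      z[miss, ] <- matrix(fill, sum(miss), 5, byrow = TRUE)
    }
    out[, (5 * k - 4):(5 * k)] <- z
  }
  structure(out, sites = sites, missing_mask = mask,
            class = c("z_matrix", "matrix", "array"))
}

# PCA scores retaining enough components for `min_variance` of the total.
# Columns are centered; scaling is off by default (z-descriptors are already
# on a common scale, and per-column scaling distorts within-cluster geometry
# when between-group variance dominates a column).
.pca_scores <- function(x, min_variance = 0.8, n_pcs = NULL, max_pcs = Inf,
                        scale. = FALSE) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 1e-12
  xc <- scale(x[, keep, drop = FALSE], scale = scale.)
  p <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  var_exp <- cumsum(p$sdev^2) / sum(p$sdev^2)
  if (is.null(n_pcs)) n_pcs <- which(var_exp >= min_variance)[1]
  n_pcs <- min(n_pcs, sum(p$sdev > 1e-10), max_pcs)
  list(scores = p$x[, seq_len(n_pcs), drop = FALSE], n_pcs = n_pcs,
       var_explained = var_exp, rotation = p$rotation, centered = xc)
}

#' Choose the number of clusters by k-means + BIC
#'
#' Runs k-means for `k = 1..k_max` on the principal-component scores of the
#' matrix and scores each solution with the BIC heuristic
#' `n * log(WSS_k / n) + k * log(n)`; the full curve is returned so an
#' elbow criterion can be applied instead.
#'
#' @param x Numeric matrix (e.g. a [encode_zmatrix()] result).
#' @param k_max Largest k to consider (must be `< nrow(x)`).
#' @param seed Integer seed (k-means restarts are seeded).
#' @param min_variance Cumulative variance retained by the PCA step.  For
#'   cluster-number selection all variance is kept by default, so the PCA
#'   is only a rotation and k-means sees the full-space distances.
#' @return List: `k` (argmin of BIC), `bic` (curve), `cluster`
#'   (assignments at the chosen k), `n_pcs`.
#' @export
select_k <- function(x, k_max = 8, seed = 1, min_variance = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("untestable: need at least 3 rows")
  k_max <- min(k_max, n - 1L)
  pc <- .pca_scores(x, min_variance)
  set.seed(seed)
  fits <- lapply(seq_len(k_max), function(k) {
    if (k == 1) {
      list(tot.withinss = sum(scale(pc$scores, scale = FALSE)^2),
           cluster = rep(1L, n))
    } else {
      stats::kmeans(pc$scores, centers = k, nstart = 20, iter.max = 50)
    }
  })
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  wss <- pmax(wss, 1e-12)
  bic <- n * log(wss / n) + seq_len(k_max) * log(n)
  k <- which.min(bic)
  list(k = k, bic = bic, wss = wss, cluster = fits[[k]]$cluster,
       n_pcs = pc$n_pcs)
}

#' Discriminant analysis of principal components
#'
#' Center/scale, reduce by PCA (retaining the minimum number of components
#' explaining at least `min_variance` of the variance, capped at
#' `n - length(unique(groups))`), then run linear discriminant analysis on
#' the retained scores.  Group labels may come from [select_k()] clusters
#' or be supplied (e.g. paralog identity, lineage).
#'
#' @param x Numeric matrix (taxa x descriptors).
#' @param groups Group labels (length `nrow(x)`, at least 2 distinct).
#' @param n_pcs Number of PCs to retain, or `"auto"` (default).
#' @param min_variance Variance-retention rule for `"auto"`.
#' @return Object of class `dapc_fit`: `scores` (discriminant
#'   coordinates), `posterior` (group membership probabilities),
#'   `assigned`, `accuracy` (reassignment rate), `n_pcs`,
#'   `var_explained`.
#' @export
dapc <- function(x, groups, n_pcs = "auto", min_variance = 0.8) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (identical(n_pcs, "auto")) n_pcs <- NULL
  else if (n_pcs < 1) stop("configuration error: n_pcs must be >= 1")
  cap <- max(1L, nrow(x) - nlevels(groups))
  pc <- .pca_scores(x, min_variance, n_pcs = n_pcs, max_pcs = cap)
  fit <- tryCatch(MASS::lda(pc$scores, grouping = groups),
                  error = function(e)
                    stop("rank error in discriminant step (groups with ",
                         "identical rows?): reduce n_pcs. [",
                         conditionMessage(e), "]"))
  pred <- stats::predict(fit, pc$scores)
  acc <- mean(pred$class == groups)
  structure(list(scores = pred$x, posterior = pred$posterior,
                 assigned = pred$class, groups = groups,
                 accuracy = acc, n_pcs = pc$n_pcs,
                 var_explained = pc$var_explained[pc$n_pcs],
                 lda = fit),
            class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat(sprintf("DAPC: %d PCs retained (%.1f%% variance), %d groups, reassignment accuracy %.1f%%\n",
              x$n_pcs, 100 * x$var_explained, nlevels(x$groups),
              100 * x$accuracy))
  invisible(x)
}
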