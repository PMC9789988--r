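#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / (length_kb * library_size / 1e6)`.
#'
#' @param count Read counts (>= 0).
#' @param length_kb Gene length in kilobases (> 0).
#' @param library_size Total mapped reads in the library (> 0).
#' @return RPKM values (vectorized).
#' @examples
#' rpkm(10, 2, 1e6)  # 5
#' @export
rpkm <- function(count, length_kb, library_size) {
  if (any(length_kb <= 0)) stop("value error: gene length must be > 0")
  if (any(library_size <= 0)) stop("value error: library size must be > 0")
  count / (length_kb * library_size / 1e6)
}

#' Transcripts per million from RPKM
#'
#' `TPM = 1e6 * RPKM / sum(RPKM)`, the sum running over the normalization
#' universe (all genes of the tissue's transcriptome, not just the focal
#' family).  Invariant to uniform rescaling of the RPKM vector.
#'
#' @param rpkm_vector RPKM values over the normalization universe.
#' @return TPM vector summing to 1e6.
#' @examples
#' tpm_from_rpkm(c(2, 3, 5))
#' @export
tpm_from_rpkm <- function(rpkm_vector) {
  s <- sum(rpkm_vector)
  if (!is.finite(s) || s <= 0)
    stop("value error: RPKM vector sums to zero; TPM undefined")
  1e6 * rpkm_vector / s
}

#' Per-species TPM table from counts and lengths
#'
#' @param counts Data frame with columns `gene`, `tissue`, `count` (one
#'   species).
#' @param lengths Data frame with columns `gene`, `length_kb`.
#' @return Matrix gene x tissue of TPM values (each column sums to 1e6).
#' @export
tpm_table <- function(counts, lengths) {
  genes <- unique(counts$gene)
  tissues <- unique(counts$tissue)
  len <- lengths$length_kb[match(genes, lengths$gene)]
  if (any(is.na(len))) stop("missing gene length for: ",
                            genes[is.na(len)][1])
  out <- matrix(NA_real_, length(genes), length(tissues),
                dimnames = list(genes, tissues))
  for (ts in tissues) {
    d <- counts[counts$tissue == ts, ]
    cnt <- d$count[match(genes, d$gene)]
    cnt[is.na(cnt)] <- 0
    lib <- sum(cnt)
    out[, ts] <- tpm_from_rpkm(rpkm(cnt, len, lib))
  }
  out
}

#' Paralog-by-tissue median TPM matrix
#'
#' For each (paralog, tissue) cell, the median TPM over the species that
#' possess the paralog; species lacking it are excluded rather than
#' counted as zero, and a cell with no observations is `NA` (missing), not
#' zero.
#'
#' @param tpm_tables Named list (by species) of gene x tissue TPM matrices
#'   (see [tpm_table()]).
#' @param paralog_map Data frame with columns `species`, `gene`, `paralog`.
#' @return Matrix paralog x tissue of median TPM, `NA` for empty cells.
#' @export
median_heatmap <- function(tpm_tables, paralog_map) {
  paralogs <- sort(unique(paralog_map$paralog))
  tissues <- unique(unlist(lapply(tpm_tables, colnames)))
  out <- matrix(NA_real_, length(paralogs), length(tissues),
                dimnames = list(paralogs, tissues))
  acc <- vector("list", length(paralogs) * length(tissues))
  dim(acc) <- c(length(paralogs), length(tissues))
  for (sp in names(tpm_tables)) {
    tab <- tpm_tables[[sp]]
    pm <- paralog_map[paralog_map$species == sp, ]
    for (r in seq_len(nrow(pm))) {
      g <- pm$gene[r]
      if (!g %in% rownames(tab)) next
      i <- match(pm$paralog[r], paralogs)
      for (ts in colnames(tab)) {
        j <- match(ts, tissues)
        acc[[i, j]] <- c(acc[[i, j]], tab[g, ts])
      }
    }
  }
  for (i in seq_along(paralogs)) for (j in seq_along(tissues)) {
    v <- acc[[i, j]]
    if (length(v)) out[i, j] <- stats::median(v)
  }
  out
}

#' Write a heatmap matrix as CSV
#'
#' @param mat Matrix from [median_heatmap()].
#' @param path Output path.
#' @export
write_heatmap_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}
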