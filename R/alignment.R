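#' Construct an in-frame codon alignment
#'
#' Codon alignments are the central sequence container: a matrix of codon
#' states (sense codon, whole-codon gap `"---"`, or ambiguous) with taxa as
#' rows and 1-based codon columns ("MSA codons").  A codon containing any
#' gap or ambiguity character is treated as fully missing at that site.
#'
#' @param sequences Named character vector of nucleotide sequences (equal
#'   length, length divisible by 3), or a character matrix of codon triplets
#'   with row names.
#' @param code Genetic code, see [standard_genetic_code()].
#' @param allow_stops Permit internal stop codons (default `FALSE`).
#' @return An object of class `codon_alignment`: list with `taxa`, `codons`
#'   (character matrix taxa x sites), `n_codons`.
#' @export
codon_alignment <- function(sequences, code = standard_genetic_code(),
                            allow_stops = FALSE) {
  if (is.matrix(sequences)) {
    codons <- toupper(sequences)
  } else {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("all sequences must have equal length")
    off <- which(lens %% 3L != 0L)
    if (length(off))
      stop(sprintf("frame error: sequence '%s' has length %d, not divisible by 3",
                   names(sequences)[off[1]], lens[off[1]]))
    codons <- t(vapply(toupper(sequences), function(s) {
      substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    }, character(lens[1] / 3L)))
    if (lens[1] == 3L) {
      codons <- matrix(codons, ncol = 1L,
                       dimnames = list(names(sequences), NULL))
    }
  }
  taxa <- rownames(codons)
  if (anyDuplicated(taxa))
    stop(sprintf("identity error: duplicate taxon '%s'",
                 taxa[duplicated(taxa)][1]))
  if (!allow_stops) {
    is_stop <- matrix(codons %in% code$stop_codons, nrow = nrow(codons))
    # a terminal stop is tolerated and recoded as missing; internal stops are not
    internal <- is_stop
    internal[, ncol(internal)] <- FALSE
    if (any(internal)) {
      w <- which(internal, arr.ind = TRUE)[1, ]
      stop(sprintf("content error: internal stop codon in '%s' at codon %d",
                   taxa[w[1]], w[2]))
    }
    codons[is_stop] <- "---"
  }
  structure(list(taxa = taxa, codons = codons, n_codons = ncol(codons)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d taxa x %d codons\n",
              length(x$taxa), x$n_codons))
  cat("Taxa:", paste(utils::head(x$taxa, 6), collapse = ", "),
      if (length(x$taxa) > 6) "..." else "", "\n")
  invisible(x)
}

#' Read an in-frame codon FASTA alignment
#'
#' @param path Path to a FASTA file of aligned coding sequences.
#' @inheritParams codon_alignment
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(path, code = standard_genetic_code(),
                             allow_stops = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- ape::read.FASTA(path)
  seqs <- vapply(as.character(x), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  codon_alignment(seqs, code = code, allow_stops = allow_stops)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output file path.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  writeLines(paste0(">", aln$taxa, "\n", seqs), path)
  invisible(path)
}

# integer codon states over the 61 sense codons; NA = gap/ambiguous/missing
.codon_indices <- function(aln, code = standard_genetic_code()) {
  idx <- match(aln$codons, code$sense_codons)
  matrix(idx, nrow = nrow(aln$codons), dimnames = dimnames(aln$codons))
}

#' Translate a codon alignment to a protein alignment
#'
#' @param aln A [codon_alignment()].
#' @param code Genetic code.
#' @return Character matrix of one-letter residues (taxa x sites); `"-"` for
#'   whole-codon gaps, `"X"` for ambiguous codons.
#' @export
translate_alignment <- function(aln, code = standard_genetic_code()) {
  v <- aln$codons
  aa <- unname(code$codon_to_aa[v])
  miss <- is.na(aa)
  aa[miss] <- ifelse(grepl("-", v[miss], fixed = TRUE), "-", "X")
  matrix(aa, nrow = nrow(v), dimnames = dimnames(v))
}

# observed codon frequencies under the chosen frequency model
.codon_frequencies <- function(aln, freq_model = c("F3x4", "F1x4", "equal"),
                               code = standard_genetic_code()) {
  freq_model <- match.arg(freq_model)
  sense <- code$sense_codons
  n <- length(sense)
  if (freq_model == "equal") {
    pi <- rep(1 / n, n)
  } else {
    obs <- aln$codons[aln$codons %in% sense]
    mat <- do.call(rbind, strsplit(obs, ""))
    bases <- c("A", "C", "G", "T")
    sense_mat <- do.call(rbind, strsplit(sense, ""))
    if (freq_model == "F1x4") {
      f <- table(factor(mat, levels = bases))
      f <- as.numeric(f) / sum(f)
      pi <- f[match(sense_mat[, 1], bases)] *
        f[match(sense_mat[, 2], bases)] *
        f[match(sense_mat[, 3], bases)]
    } else {
      pi <- rep(1, n)
      for (p in 1:3) {
        f <- table(factor(mat[, p], levels = bases))
        f <- as.numeric(f) / sum(f)
        pi <- pi * f[match(sense_mat[, p], bases)]
      }
    }
    pi <- pmax(pi, 1e-10)
    pi <- pi / sum(pi)
  }
  names(pi) <- sense
  pi
}

# site-pattern compression: unique columns with counts
.site_patterns <- function(states) {
  keys <- apply(states, 2, paste, collapse = "\r")
  u <- !duplicated(keys)
  map <- match(keys, keys[u])
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(tabulate(map, nbins = sum(u))),
       map = map)
}
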