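#' The standard genetic code
#'
#' Returns the standard (universal) genetic code as used throughout the
#' package: a translation table over all 64 codons and the ordered list of
#' the 61 sense (non-stop) codons that index the states of the codon
#' substitution model.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character vector of length 64, `"*"` marks a stop),
#'   `sense_codons` (character vector of length 61, in alphabetical codon
#'   order), and `stop_codons`.
#' @examples
#' code <- standard_genetic_code()
#' length(code$sense_codons)  # 61
#' @export
standard_genetic_code <- function() {
  if (is.null(.ohnosel_cache$code))
    assign("code", .build_standard_code(), envir = .ohnosel_cache)
  .ohnosel_cache$code
}

.build_standard_code <- function() {
  bases <- c("T", "C", "A", "G")
  # rows of the classical codon table, TTT, TTC, TTA, TTG, CTT, ...
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 1L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons[k] <- paste0(b1, b2, b3); k <- k + 1L
  }
  names(aa) <- codons
  ord <- sort(codons)
  aa <- aa[ord]
  sense <- names(aa)[aa != "*"]
  structure(list(codon_to_aa = aa,
                 sense_codons = sense,
                 stop_codons = names(aa)[aa == "*"]),
            class = "genetic_code")
}

#' Translate a codon
#'
#' @param codon Character vector of nucleotide triplets over `{A,C,G,T}`
#'   (case-insensitive).
#' @param code A [standard_genetic_code()] object.
#' @return One-letter amino-acid codes; `"*"` for stop codons, `"X"` for
#'   codons containing ambiguous or gap characters.
#' @examples
#' translate_codon(c("ATG", "TAA", "ATT", "ATC"))
#' @export
translate_codon <- function(codon, code = standard_genetic_code()) {
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L
  if (any(bad)) stop("codons must be nucleotide triplets")
  aa <- unname(code$codon_to_aa[codon])
  aa[is.na(aa)] <- "X"
  aa
}

# single-nucleotide neighbour structure of the 61 sense codons, used by the
# rate matrix, the counting test, and the simulators
.codon_pairs <- function(code = standard_genetic_code()) {
  cache <- .ohnosel_cache
  if (!is.null(cache$pairs)) return(cache$pairs)
  sense <- code$sense_codons
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  purines <- c("A", "G")
  i_idx <- integer(0); j_idx <- integer(0); ts <- logical(0); syn <- logical(0)
  aa <- code$codon_to_aa[sense]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- which(mat[i, ] != mat[j, ])
    if (length(diff) != 1L) next
    b1 <- mat[i, diff]; b2 <- mat[j, diff]
    i_idx <- c(i_idx, i); j_idx <- c(j_idx, j)
    ts <- c(ts, (b1 %in% purines) == (b2 %in% purines))
    syn <- c(syn, aa[i] == aa[j])
  }
  pairs <- list(i = i_idx, j = j_idx, transition = ts, synonymous = syn)
  assign("pairs", pairs, envir = cache)
  pairs
}

.ohnosel_cache <- new.env(parent = emptyenv())
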