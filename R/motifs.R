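# Motif scanning and domain mapping for HIF-alpha style proteins: the
# LxxLAP prolyl-hydroxylation motif of the oxygen-dependent degradation
# domains and the C-terminal CEVN asparaginyl-hydroxylation motif.

#' Scan a protein sequence for the LxxLAP degradation motif
#'
#' Finds all (possibly overlapping) occurrences of `L-x-x-L-A-P`, the
#' canonical target of the oxygen-sensing prolyl hydroxylases.
#'
#' @param sequence Protein sequence (single string, one-letter codes).
#' @param id Optional sequence identifier carried into the result.
#' @return Data frame with `id`, `start` (1-based), `match`, `motif`.
#' @examples
#' scan_lxxlap("MSLTLLAPAA")
#' @export
scan_lxxlap <- function(sequence, id = NA_character_) {
  s <- toupper(sequence)
  hits <- gregexpr("(?=L..LAP)", s, perl = TRUE)[[1]]
  if (hits[1] == -1) {
    return(data.frame(id = character(0), start = integer(0),
                      match = character(0), motif = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(hits)
  data.frame(id = id, start = starts,
             match = substring(s, starts, starts + 5L),
             motif = "LxxLAP", stringsAsFactors = FALSE)
}

#' Scan the C-terminus for the CEVN asparaginyl-hydroxylation motif
#'
#' Searches the last `window` residues for an exact `CEVN`; if absent, a
#' single-mismatch near-match is reported as a degraded motif naming the
#' substitution (e.g. `N->T` for the salmonid case where the target
#' asparagine is replaced by threonine).
#'
#' @param sequence Protein sequence.
#' @param window Number of C-terminal residues scanned (default 50;
#'   sequences shorter than the window are scanned in full).
#' @param id Optional sequence identifier.
#' @return Data frame with `id`, `start` (position in the full sequence),
#'   `match`, `motif` (`"CEVN"` or `"CEVN-degraded"`), `substitution`
#'   (`NA` for exact hits).
#' @export
scan_cterm_asn_motif <- function(sequence, window = 50, id = NA_character_) {
  s <- toupper(sequence)
  n <- nchar(s)
  from <- max(1L, n - as.integer(window) + 1L)
  tail_s <- substring(s, from, n)
  empty <- data.frame(id = character(0), start = integer(0),
                      match = character(0), motif = character(0),
                      substitution = character(0), stringsAsFactors = FALSE)
  exact <- regexpr("CEVN", tail_s, fixed = TRUE)
  if (exact != -1) {
    return(data.frame(id = id, start = from + as.integer(exact) - 1L,
                      match = "CEVN", motif = "CEVN",
                      substitution = NA_character_,
                      stringsAsFactors = FALSE))
  }
  pattern <- strsplit("CEVN", "")[[1]]
  best <- NULL
  for (p in seq_len(max(0, nchar(tail_s) - 3L))) {
    cand <- strsplit(substring(tail_s, p, p + 3L), "")[[1]]
    mm <- which(cand != pattern)
    if (length(mm) == 1L) {
      sub <- sprintf("%s->%s", pattern[mm], cand[mm])
      hit <- data.frame(id = id, start = from + p - 1L,
                        match = paste(cand, collapse = ""),
                        motif = "CEVN-degraded", substitution = sub,
                        stringsAsFactors = FALSE)
      if (is.null(best)) best <- hit
    }
  }
  if (is.null(best)) empty else best
}

#' Map an alignment column to a reference-sequence residue
#'
#' Converts a 1-based alignment column ("MSA codon") to the residue number
#' of an ungapped reference sequence (e.g. human HIF1-alpha, to compare
#' selected sites with known post-translational modification sites): the
#' count of non-gap reference characters up to and including the column.
#'
#' @param msa Protein alignment matrix (taxa x columns) or
#'   [codon_alignment()].
#' @param column 1-based alignment column.
#' @param reference Taxon name of the reference row.
#' @return Integer residue index, or `NA` if the reference has a gap at
#'   that column.
#' @export
map_column_to_reference <- function(msa, column, reference) {
  if (inherits(msa, "codon_alignment")) msa <- translate_alignment(msa)
  if (!reference %in% rownames(msa)) stop("reference taxon not in alignment")
  if (column < 1 || column > ncol(msa))
    stop("index error: column outside 1..", ncol(msa))
  row <- msa[reference, ]
  if (row[column] == "-") return(NA_integer_)
  sum(row[seq_len(column)] != "-")
}

#' Domain annotation for a reference protein
#'
#' @param intervals Named list of `c(start, end)` 1-based inclusive residue
#'   ranges on the reference (e.g. `bHLH`, `PAS-A`, `PAS-B`, `NODD`,
#'   `CODD`, `NTAD`, `CTAD`, `LZIP`).
#' @param reference Reference taxon name.
#' @return Object of class `domain_annotation`.
#' @export
domain_annotation <- function(intervals, reference = NA_character_) {
  if (is.null(names(intervals)) || anyDuplicated(names(intervals)))
    stop("domain names must be unique")
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    if (length(iv) != 2 || iv[2] < iv[1] || iv[1] < 1)
      stop("bad interval for domain ", nm)
  }
  ivs <- do.call(rbind, intervals)
  ord <- order(ivs[, 1])
  if (any(ivs[ord, 1][-1] <= ivs[ord, 2][-nrow(ivs)]))
    stop("configuration error: overlapping domain intervals")
  structure(list(intervals = intervals, reference = reference),
            class = "domain_annotation")
}

#' Read a domain annotation from a plain-text config
#'
#' One domain per line, `name = start-end` (blank lines and `#` comments
#' ignored).
#'
#' @param path Config path.
#' @param reference Reference taxon name.
#' @return A [domain_annotation()].
#' @export
read_domain_config <- function(path, reference = NA_character_) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  intervals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)$", ln))[[1]]
    if (length(m) != 4) stop("cannot parse domain config line: ", ln)
    intervals[[m[2]]] <- c(as.integer(m[3]), as.integer(m[4]))
  }
  domain_annotation(intervals, reference)
}

#' Tally selected sites by structural domain
#'
#' Assigns each site (in reference-residue coordinates, see
#' [map_column_to_reference()]) to the unique domain interval containing
#' it; sites outside every interval are counted as `"linker"`.
#'
#' @param sites Integer vector of reference residue positions.
#' @param annotation A [domain_annotation()].
#' @return Named integer vector of counts (one entry per domain plus
#'   `linker`); sums to `length(sites)`.
#' @export
tally_sites_by_domain <- function(sites, annotation) {
  stopifnot(inherits(annotation, "domain_annotation"))
  doms <- names(annotation$intervals)
  counts <- stats::setNames(integer(length(doms) + 1L), c(doms, "linker"))
  for (s in sites) {
    hit <- "linker"
    for (nm in doms) {
      iv <- annotation$intervals[[nm]]
      if (s >= iv[1] && s <= iv[2]) { hit <- nm; break }
    }
    counts[hit] <- counts[hit] + 1L
  }
  counts
}
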