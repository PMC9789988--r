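#' Gene neighborhood around a focal gene
#'
#' The synteny unit of comparison: up to 10 flanking genes upstream
#' (offsets -10..-1) and 10 downstream (+1..+10) of a focal gene, each with
#' a gene symbol (uppercase-normalized; `"unknown"` for unidentifiable open
#' reading frames) and a strand.
#'
#' @param species Species name.
#' @param focal_gene Focal gene identifier.
#' @param offsets Integer offsets in `-10..-1, 1..10` (unique).
#' @param symbols Gene symbols (or `"unknown"`).
#' @param strands `"+"`/`"-"` per flank (default all `"+"`).
#' @return Object of class `gene_neighborhood`.
#' @export
gene_neighborhood <- function(species, focal_gene, offsets, symbols,
                              strands = NULL) {
  offsets <- as.integer(offsets)
  if (anyDuplicated(offsets)) stop("offsets must be unique")
  if (any(offsets == 0L) || any(abs(offsets) > 10L))
    stop("offsets must lie in -10..-1, 1..10")
  if (length(symbols) != length(offsets)) stop("one symbol per offset")
  if (is.null(strands)) strands <- rep("+", length(offsets))
  symbols <- toupper(symbols)
  symbols[symbols == "UNKNOWN"] <- "unknown"
  ord <- order(offsets)
  structure(list(species = species, focal_gene = focal_gene,
                 offsets = offsets[ord], symbols = symbols[ord],
                 strands = strands[ord]),
            class = "gene_neighborhood")
}

#' @export
print.gene_neighborhood <- function(x, ...) {
  cat(sprintf("Neighborhood of %s [%s]: %d flanks (%d known)\n",
              x$focal_gene, x$species, length(x$offsets),
              sum(x$symbols != "unknown")))
  invisible(x)
}

.known_symbols <- function(n) unique(n$symbols[n$symbols != "unknown"])

#' Number of shared flanking genes
#'
#' The size of the intersection of the two neighborhoods' known gene-symbol
#' sets.  `"unknown"` entries never match and duplicated symbols within one
#' window count once; order and strand are ignored (they matter only for
#' [conserved_run()]).
#'
#' @param n1,n2 [gene_neighborhood()] objects.
#' @return Integer in `0..20`.
#' @export
shared_flank_count <- function(n1, n2) {
  length(intersect(.known_symbols(n1), .known_symbols(n2)))
}

#' Longest conserved in-order run of flanking genes
#'
#' Walks outward from the focal gene on one side and counts how many
#' consecutive positions carry the same symbol in both neighborhoods;
#' an `"unknown"` or a mismatch breaks the run.  Strand agreement is
#' reported as an attribute but not required.
#'
#' @param n1,n2 [gene_neighborhood()] objects.
#' @param side `"up"` (offsets -1, -2, ...) or `"down"` (+1, +2, ...).
#' @return Integer run length (0..10) with attribute `strand_agreement`.
#' @export
conserved_run <- function(n1, n2, side = c("up", "down")) {
  side <- match.arg(side)
  ord <- if (side == "up") -(1:10) else 1:10
  s1 <- n1$symbols[match(ord, n1$offsets)]
  s2 <- n2$symbols[match(ord, n2$offsets)]
  run <- 0L; agree <- 0L
  for (k in seq_along(ord)) {
    if (is.na(s1[k]) || is.na(s2[k]) || s1[k] == "unknown" ||
        s1[k] != s2[k]) break
    run <- run + 1L
    t1 <- n1$strands[match(ord[k], n1$offsets)]
    t2 <- n2$strands[match(ord[k], n2$offsets)]
    if (identical(t1, t2)) agree <- agree + 1L
  }
  structure(run, strand_agreement = agree)
}

.assignment <- function(ids, labels, scores, reference) {
  structure(list(paralogs = ids, labels = labels, scores = scores,
                 reference = reference),
            class = "paralog_assignment")
}

#' @export
print.paralog_assignment <- function(x, ...) {
  cat(sprintf("Paralog labels (vs %s reference):\n", x$reference))
  for (i in seq_along(x$paralogs))
    cat(sprintf("  %s -> %s (shared flanks: %d)\n", x$paralogs[i],
                x$labels[i], x$scores[i]))
  invisible(x)
}

#' Assign a/b labels to a post-TGD paralog pair
#'
#' Implements the phylogenetically informed naming rule for paralogs from
#' the teleost genome duplication: when at least one lineage retains both
#' paralogs, the "a" form is the one sharing more flanking genes with the
#' ancestral (pre-duplication, e.g. spotted gar) neighborhood; ties are
#' left unresolved.  When no lineage retains both copies the suffix is
#' withheld ("unsuffixed"), because the copy's identity cannot be
#' established.
#'
#' @param p1,p2 [gene_neighborhood()] objects for the two paralogs.
#' @param ancestral Neighborhood of the unduplicated ancestral ortholog.
#' @param retained_in_any_lineage_both Does at least one lineage retain
#'   both paralogs? (default `TRUE`).
#' @return A `paralog_assignment`.
#' @export
assign_tgd_labels <- function(p1, p2, ancestral,
                              retained_in_any_lineage_both = TRUE) {
  if (missing(ancestral) || is.null(ancestral))
    stop("configuration error: ancestral reference neighborhood required")
  s1 <- shared_flank_count(p1, ancestral)
  s2 <- shared_flank_count(p2, ancestral)
  ids <- c(p1$focal_gene, p2$focal_gene)
  if (!retained_in_any_lineage_both) {
    return(.assignment(ids, c("unsuffixed", "unsuffixed"), c(s1, s2),
                       "ancestral"))
  }
  labels <- if (s1 > s2) c("a", "b") else if (s2 > s1) c("b", "a")
    else c("unresolved", "unresolved")
  .assignment(ids, labels, c(s1, s2), "ancestral")
}

#' Assign s1/s2 labels to a post-SGD paralog pair
#'
#' Salmonid-specific duplicates: the copy sharing more flanking genes with
#' the sister-group (Esociformes) ortholog is "s1", the other "s2"; ties
#' are unresolved.
#'
#' @param p1,p2 [gene_neighborhood()] objects for the two paralogs.
#' @param sister_group_ref Neighborhood of the sister-group ortholog.
#' @return A `paralog_assignment`.
#' @export
assign_sgd_labels <- function(p1, p2, sister_group_ref) {
  if (missing(sister_group_ref) || is.null(sister_group_ref))
    stop("configuration error: sister-group reference neighborhood required")
  s1 <- shared_flank_count(p1, sister_group_ref)
  s2 <- shared_flank_count(p2, sister_group_ref)
  ids <- c(p1$focal_gene, p2$focal_gene)
  labels <- if (s1 > s2) c("s1", "s2") else if (s2 > s1) c("s2", "s1")
    else c("unresolved", "unresolved")
  .assignment(ids, labels, c(s1, s2), "sister-group")
}

#' Read gene neighborhoods from a TSV file
#'
#' Expected columns: `species`, `focal_gene`, `offset`, `symbol`, `strand`
#' (one row per flank slot).
#'
#' @param path TSV path.
#' @return Named list of [gene_neighborhood()] objects, keyed
#'   `"species:focal_gene"`.
#' @export
read_neighborhoods <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "focal_gene", "offset", "symbol", "strand")
  if (!all(need %in% names(df)))
    stop("neighborhood TSV must have columns: ", paste(need, collapse = ", "))
  keys <- paste(df$species, df$focal_gene, sep = ":")
  out <- lapply(split(df, keys), function(d)
    gene_neighborhood(d$species[1], d$focal_gene[1], d$offset, d$symbol,
                      d$strand))
  out
}

#' Write gene neighborhoods to a TSV file
#'
#' @param neighborhoods List of [gene_neighborhood()] objects.
#' @param path Output path.
#' @export
write_neighborhoods <- function(neighborhoods, path) {
  rows <- lapply(neighborhoods, function(n)
    data.frame(species = n$species, focal_gene = n$focal_gene,
               offset = n$offsets, symbol = n$symbols, strand = n$strands,
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
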