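#' Read a Newick tree with foreground branch tags
#'
#' Branch models need a set of "foreground" branches whose dN/dS ratio is
#' allowed to differ from the rest of the tree.  Following the convention of
#' codon-model software, a `#1` suffix on a tip or internal-node label marks
#' the branch leading to that node (and only that branch) as foreground; the
#' clade variant `#1*` on an internal node additionally propagates the flag
#' to every descendant branch.
#'
#' @param text Newick string, or `NULL` if `path` is given.
#' @param path Optional path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object with an extra logical
#'   component `foreground` aligned to the rows of `$edge`; tags are removed
#'   from the labels.
#' @examples
#' tr <- read_newick("(A#1:0.1,B:0.2);")
#' sum(tr$foreground)  # 1
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not read tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("value error: negative branch length")
  n_tip <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else
                rep("", tree$Nnode))
  clade_tag <- grepl("#1\\*$", labels)
  branch_tag <- grepl("#1$", labels) & !clade_tag
  labels_clean <- sub("#1\\*?$", "", labels)
  tree$tip.label <- labels_clean[seq_len(n_tip)]
  if (!is.null(tree$node.label)) tree$node.label <- labels_clean[-seq_len(n_tip)]

  fg <- branch_tag[tree$edge[, 2]] | clade_tag[tree$edge[, 2]]
  # clade tags propagate downwards
  for (node in which(clade_tag)) {
    fg <- fg | (tree$edge[, 1] %in% .descendant_nodes(tree, node)) |
      (tree$edge[, 1] == node)
  }
  tree$foreground <- as.logical(fg)
  tree
}

.descendant_nodes <- function(tree, node) {
  out <- integer(0)
  todo <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(todo)) {
    out <- c(out, todo)
    todo <- tree$edge[tree$edge[, 1] %in% todo, 2]
  }
  out
}

#' Write a tree with foreground tags back to Newick
#'
#' @param tree A `phylo` with optional `foreground` flags (see
#'   [read_newick()]); only single-branch `#1` tags are emitted.
#' @param path Optional output path; if `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  out <- tree
  if (!is.null(tree$foreground) && any(tree$foreground)) {
    n_tip <- length(tree$tip.label)
    if (is.null(out$node.label)) out$node.label <- rep("", tree$Nnode)
    for (e in which(tree$foreground)) {
      child <- tree$edge[e, 2]
      if (child <= n_tip) {
        out$tip.label[child] <- paste0(out$tip.label[child], "#1")
      } else {
        out$node.label[child - n_tip] <- paste0(out$node.label[child - n_tip], "#1")
      }
    }
  }
  out$foreground <- NULL
  txt <- ape::write.tree(out)
  if (!is.null(path)) { writeLines(txt, path); invisible(path) } else txt
}

#' Flag the branches of a clade as foreground
#'
#' @param tree A `phylo`.
#' @param tips Tip labels spanning the clade; the foreground set is the stem
#'   branch of their most recent common ancestor plus, if `include_clade`,
#'   all branches within the clade.
#' @param include_clade Propagate to descendant branches (default `TRUE`).
#' @return The tree with an updated `foreground` component.
#' @export
flag_foreground_clade <- function(tree, tips, include_clade = TRUE) {
  stopifnot(all(tips %in% tree$tip.label))
  n_tip <- length(tree$tip.label)
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, tips)
  }
  fg <- tree$edge[, 2] == node
  if (include_clade && node > n_tip)
    fg <- fg | tree$edge[, 1] %in% c(node, .descendant_nodes(tree, node))
  tree$foreground <- fg
  tree
}
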