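#' Read a Newick tree with an optional foreground branch mark
#'
#' Branch-site analyses designate one foreground branch. The mark uses the
#' widely understood `#1` suffix on the label of a tip or internal node: the
#' marked branch is the stem branch leading to that node/clade. At most one
#' mark is allowed per tree.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An [ape::read.tree()] `phylo` object; if a mark was present, the
#'   attribute `foreground_node` holds the ape node number whose stem branch
#'   is foreground, and `#1` is stripped from the stored label.
#' @export
read_marked_tree <- function(x) {
  txt <- if (length(x) == 1L && !grepl("\\(", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stopf("could not parse Newick input")
  hit_tip <- grep("#1$", tree$tip.label)
  hit_node <- if (!is.null(tree$node.label)) grep("#1$", tree$node.label) else integer(0)
  if (length(hit_tip) + length(hit_node) > 1L) {
    stopf("more than one '#1' foreground mark in tree")
  }
  fg <- NULL
  if (length(hit_tip) == 1L) {
    tree$tip.label[hit_tip] <- sub("\\s*#1$", "", tree$tip.label[hit_tip])
    fg <- hit_tip
  } else if (length(hit_node) == 1L) {
    tree$node.label[hit_node] <- sub("\\s*#1$", "", tree$node.label[hit_node])
    fg <- ape::Ntip(tree) + hit_node
  }
  tree$tip.label <- trimws(tree$tip.label)
  attr(tree, "foreground_node") <- fg
  tree
}

#' Write a tree, restoring the foreground mark
#'
#' @param tree `phylo`, optionally carrying attribute `foreground_node`.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @export
write_marked_tree <- function(tree, path = NULL) {
  fg <- attr(tree, "foreground_node")
  if (!is.null(fg)) {
    ntip <- ape::Ntip(tree)
    if (fg <= ntip) {
      tree$tip.label[fg] <- paste0(tree$tip.label[fg], "#1")
    } else {
      if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
      tree$node.label[fg - ntip] <- paste0(tree$node.label[fg - ntip], "#1")
    }
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Mark the stem branch of a clade as foreground
#'
#' @param tree `phylo`.
#' @param taxa Tip labels of a monophyletic group (or one tip) whose stem
#'   branch is the foreground branch.
#' @return The tree with attribute `foreground_node` set.
#' @export
mark_foreground <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) stopf("taxa not in tree: %s", paste(missing, collapse = ", "))
  node <- if (length(taxa) == 1L) {
    match(taxa, tree$tip.label)
  } else {
    ape::getMRCA(tree, taxa)
  }
  tips_under <- tree$tip.label[clade_tips(tree, node)]
  if (!setequal(tips_under, taxa)) {
    stopf("clade is not monophyletic: MRCA also contains %s",
          paste(setdiff(tips_under, taxa), collapse = ", "))
  }
  attr(tree, "foreground_node") <- node
  tree
}

clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  unlist(phangorn_free_descendants(tree, node))
}

## tip indices below a node, without depending on phangorn
phangorn_free_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    n <- stack[[1]]
    stack <- stack[-1]
    if (n <= ntip) {
      out <- c(out, n)
    } else {
      stack <- c(stack, tree$edge[tree$edge[, 1] == n, 2])
    }
  }
  out
}

#' Foreground clade tip labels
#' @param tree A tree carrying attribute `foreground_node`.
#' @export
foreground_taxa <- function(tree) {
  fg <- attr(tree, "foreground_node")
  if (is.null(fg)) return(character(0))
  tree$tip.label[clade_tips(tree, fg)]
}

## edge index of the stem branch of the foreground node; 0 when unmarked
foreground_edge <- function(tree) {
  fg <- attr(tree, "foreground_node")
  if (is.null(fg)) return(0L)
  e <- which(tree$edge[, 2] == fg)
  if (length(e) != 1L) stopf("foreground node has no stem branch (is it the root?)")
  e
}

validate_tree_alignment <- function(tree, aln) {
  if (!setequal(tree$tip.label, aln$taxa)) {
    stopf("tree tips and alignment taxa differ: tree-only [%s], aln-only [%s]",
          paste(setdiff(tree$tip.label, aln$taxa), collapse = ", "),
          paste(setdiff(aln$taxa, tree$tip.label), collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stopf("negative branch lengths")
  }
  invisible(TRUE)
}
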