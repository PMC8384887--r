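#' Read a Newick tree with branch group labels
#'
#' Parses a Newick tree whose tip or internal node labels may carry
#' codeml-style `#group` tags (e.g. `(sp1#1,sp2):0.1`). A tag on a node
#' labels the edge leading to that node; a tag on an internal node can be
#' propagated to its whole subtree with `cladeTags = TRUE` (the usual
#' clade-model reading). Alternatively a two-column TSV (`taxon`, `group`)
#' maps tip branches to groups.
#'
#' @param source path to a Newick file or a Newick string.
#' @param branchMap optional path to (or data.frame of) a `taxon`/`group`
#'   TSV applied after any `#` tags.
#' @param cladeTags propagate internal-node tags to all descendant edges.
#' @return A [LabeledTree-class]; untagged edges are `background`.
#' @export
readLabeledTree <- function(source, branchMap = NULL, cladeTags = TRUE) {
  txt <- if (file.exists(source)) paste(readLines(source), collapse = "") else source
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick input")
  grab <- function(labels) {
    tag <- rep(NA_character_, length(labels))
    has <- grepl("#", labels)
    tag[has] <- sub("^.*#", "", labels[has])
    list(clean = sub("#.*$", "", labels), tag = tag)
  }
  tl <- grab(phy$tip.label)
  phy$tip.label <- tl$clean
  nl <- if (!is.null(phy$node.label)) grab(phy$node.label) else
    list(clean = character(), tag = character())
  if (length(nl$clean)) phy$node.label <- nl$clean
  ntip <- length(phy$tip.label)
  nodetag <- c(tl$tag, nl$tag)  # indexed by node number
  groups <- rep("background", nrow(phy$edge))
  # tag on a node labels its parent edge
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2]
    if (child <= length(nodetag) && !is.na(nodetag[child]))
      groups[i] <- nodetag[child]
  }
  if (cladeTags && length(nl$tag) && any(!is.na(nl$tag))) {
    for (nd in which(!is.na(nl$tag))) {
      node <- ntip + nd
      desc <- .descendantEdges(phy, node)
      groups[desc] <- nl$tag[nd]
    }
  }
  if (!is.null(branchMap)) {
    bm <- if (is.character(branchMap))
      utils::read.delim(branchMap, stringsAsFactors = FALSE) else branchMap
    if (!all(c("taxon", "group") %in% names(bm)))
      stop("branchMap needs columns taxon, group")
    miss <- setdiff(bm$taxon, phy$tip.label)
    if (length(miss))
      stop("branchMap names taxa absent from the tree: ",
           paste(miss, collapse = ", "))
    for (r in seq_len(nrow(bm))) {
      tipno <- match(bm$taxon[r], phy$tip.label)
      groups[phy$edge[, 2] == tipno] <- as.character(bm$group[r])
    }
  }
  gn <- c("background", setdiff(unique(groups), "background"))
  LabeledTree(phy, groups, groupNames = gn)
}

# edge indices of all edges inside the clade rooted at `node` (stem included)
.descendantEdges <- function(phy, node) {
  out <- integer()
  stem <- which(phy$edge[, 2] == node)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- which(phy$edge[, 1] == nd)
    out <- c(out, kids)
    stack <- c(stack, phy$edge[kids, 2])
  }
  c(stem, out)
}

#' Label a clade of a tree as a branch group
#'
#' @param tree a [LabeledTree-class] (or ape `phylo`).
#' @param tipsInClade tip labels spanning the clade (their MRCA's subtree
#'   is labeled); a single tip labels just that terminal branch.
#' @param group group name to assign.
#' @param includeStem label the stem branch of the clade too.
#' @return An updated [LabeledTree-class].
#' @export
labelClade <- function(tree, tipsInClade, group, includeStem = TRUE) {
  if (inherits(tree, "phylo")) tree <- LabeledTree(tree)
  phy <- treePhylo(tree)
  tipno <- match(tipsInClade, phy$tip.label)
  if (anyNA(tipno))
    stop("tips not in tree: ",
         paste(tipsInClade[is.na(tipno)], collapse = ", "))
  gn <- groupNames(tree)
  if (!group %in% gn) gn <- c(gn, group)
  gid <- match(group, gn)
  groups <- edgeGroups(tree)
  if (length(tipno) == 1L) {
    edges <- which(phy$edge[, 2] == tipno)
  } else {
    mrca <- ape::getMRCA(phy, tipno)
    edges <- .descendantEdges(phy, mrca)
    if (!includeStem) edges <- setdiff(edges, which(phy$edge[, 2] == mrca))
  }
  groups[edges] <- gid
  LabeledTree(phy, groups, groupNames = gn)
}

#' Write a labeled tree with codeml-style tags
#'
#' @param tree a [LabeledTree-class].
#' @param path output file; the non-background tip groups are written as
#'   `taxon#group` tags.
#' @return The path, invisibly.
#' @export
writeLabeledTree <- function(tree, path) {
  phy <- treePhylo(tree)
  groups <- edgeGroups(tree)
  gn <- groupNames(tree)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (is.null(phy$node.label)) phy$node.label <- rep("", nnode)
  for (e in seq_along(groups)) {
    if (groups[e] == 1L) next
    child <- phy$edge[e, 2]
    tag <- paste0("#", gn[groups[e]])
    if (child <= ntip)
      phy$tip.label[child] <- paste0(phy$tip.label[child], tag)
    else
      phy$node.label[child - ntip] <- paste0(phy$node.label[child - ntip],
                                             tag)
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
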