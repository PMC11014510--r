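#' Read a rooted tree from a newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that validates the properties the
#' Dollo machinery relies on: a single rooted tree, unique leaf labels, and
#' (optionally) branch lengths. Polytomies are allowed and preserved.
#'
#' @param text Newick string (used when `file` is `NULL`).
#' @param file Path to a newick file.
#' @return An object of class `phylo` (rooted, possibly multifurcating).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("could not parse newick input")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, got several")
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  tr
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

## internal: children list indexed by node number (ape numbering:
## leaves 1..n, root n+1, internals n+1..n+m)
phylo_children <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

phylo_root <- function(tree) ape::Ntip(tree) + 1L

## internal: postorder node sequence (children before parents)
phylo_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  c(tr$edge[, 2][!duplicated(tr$edge[, 2])], phylo_root(tree))
}

#' Stable branch identifiers
#'
#' Every non-root node (equivalently, the branch above it) is identified by
#' the sorted leaf labels of its clade joined with `"|"`. Leaf branches are
#' simply the leaf label. These identifiers survive re-serialization of the
#' tree, so loss maps keyed by them remain valid across newick round trips.
#'
#' @param tree A `phylo` object.
#' @return Named character vector: names are node numbers (as character),
#'   values are branch ids. The root has no branch and is omitted.
#' @export
branch_ids <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- phylo_children(tree)
  clade <- vector("list", nn)
  for (v in phylo_postorder(tree)) {
    clade[[v]] <- if (v <= ntip) tree$tip.label[v] else
      sort(unlist(clade[kids[[v]]], use.names = FALSE))
  }
  ids <- vapply(clade, paste, "", collapse = "|")
  ids <- ids[-phylo_root(tree)]
  names(ids) <- setdiff(seq_len(nn), phylo_root(tree))
  ids
}

## internal: node number for a branch id, NA if absent
branch_node <- function(tree, branch_id) {
  ids <- branch_ids(tree)
  hit <- names(ids)[ids == branch_id]
  if (length(hit) == 0) return(NA_integer_)
  as.integer(hit[1])
}

#' Collapse an internal branch into a polytomy
#'
#' Removes the branch above an internal node, re-attaching that node's
#' children to its parent. The removed branch's length is discarded; all
#' other branch lengths are preserved. The result may be multifurcating and
#' is scored with hard-polytomy semantics by [dollo_fit()].
#'
#' @param tree A `phylo` object.
#' @param branch_id Branch identifier (see [branch_ids()]); must name an
#'   internal, non-root branch.
#' @return A `phylo` object with one fewer internal node.
#' @export
collapse_branch <- function(tree, branch_id) {
  v <- branch_node(tree, branch_id)
  if (is.na(v)) stop("no branch with id '", branch_id, "'")
  if (v <= ape::Ntip(tree)) stop("cannot collapse a leaf branch: ", branch_id)
  kids <- phylo_children(tree)
  has_len <- !is.null(tree$edge.length)
  lens <- if (has_len) {
    le <- numeric(ape::Ntip(tree) + tree$Nnode)
    le[tree$edge[, 2]] <- tree$edge.length
    le
  } else NULL
  build <- function(node) {
    ch <- kids[[node]]
    if (length(ch) == 0) {
      s <- tree$tip.label[node]
    } else {
      ch_expanded <- unlist(lapply(ch, function(c) if (c == v) kids[[v]] else c))
      s <- paste0("(", paste(vapply(ch_expanded, build, ""), collapse = ","), ")")
    }
    if (node != phylo_root(tree) && node != v && has_len)
      s <- paste0(s, ":", format(lens[node], digits = 15))
    s
  }
  ape::read.tree(text = paste0(build(phylo_root(tree)), ";"))
}

#' Canonical topology string
#'
#' Serializes the unweighted rooted topology with children sorted by their
#' smallest leaf label, so two trees have equal canonical strings iff they
#' are the same rooted topology. Used to deduplicate co-optimal trees.
#'
#' @param tree A `phylo` object.
#' @return A character scalar.
#' @export
canonical_topology <- function(tree) {
  kids <- phylo_children(tree)
  ntip <- ape::Ntip(tree)
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    parts <- sort(vapply(kids[[node]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(phylo_root(tree)), ";")
}

## internal: branch lengths keyed by branch id (child-node keyed)
branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ids <- branch_ids(tree)
  le <- numeric(length(ids))
  names(le) <- ids
  for (i in seq_len(nrow(tree$edge))) {
    ch <- as.character(tree$edge[i, 2])
    le[ids[[ch]]] <- tree$edge.length[i]
  }
  le
}
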