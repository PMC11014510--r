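## Dollo parsimony engine.
##
## A character evolves under Dollo when it can be gained once (0 -> 1) and
## lost irreversibly any number of times (1 -> 0). The minimum-loss
## explanation of a binary character on a rooted tree has a closed
## combinatorial form: with the gene forced present at the root, losses sit
## on the maximal clades whose observed leaves are all 0 (clades of only
## '?' stay present and contribute nothing); with a free gain, the gain
## sits above the MRCA of the 1-leaves and the same counting applies
## strictly inside that subtree. Both modes are evaluated here with one
## vectorized post-order sweep over all characters at once.

## internal: uniform tree structure (works for ape phylo and for the
## search's nested-list trees): parent vector (0 at root), postorder node
## order, leaf -> species row map, number of nodes.
tree_struct <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  parent <- integer(nn)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  tr <- ape::reorder.phylo(tree, "postorder")
  post <- tr$edge[, 2]          # children before parents; root excluded
  list(ntip = ntip, nn = nn, root = ntip + 1L, parent = parent,
       postorder = post, tip.label = tree$tip.label)
}

## internal: per-node observed 0/1 counts below each node, for a
## leaves x patterns state matrix (rows in tip order; NA = '?').
node_counts <- function(st, states) {
  P <- ncol(states)
  n0 <- matrix(0L, st$nn, P)
  n1 <- matrix(0L, st$nn, P)
  n0[seq_len(st$ntip), ] <- !is.na(states) & states == 0L
  n1[seq_len(st$ntip), ] <- !is.na(states) & states == 1L
  for (v in st$postorder) {
    p <- st$parent[v]
    n0[p, ] <- n0[p, ] + n0[v, ]
    n1[p, ] <- n1[p, ] + n1[v, ]
  }
  list(n0 = n0, n1 = n1)
}

## internal: loss-branch indicator matrix (nodes x patterns) under the
## Dollo minimum. root_present = TRUE forces the gene present at the root
## (an all-0 character then needs one loss per root child); FALSE places a
## single free gain above the MRCA of the 1-leaves.
dollo_loss_matrix <- function(st, states, root_present = TRUE) {
  cn <- node_counts(st, states)
  n0 <- cn$n0; n1 <- cn$n1
  all0 <- n1 == 0L & n0 > 0L
  P <- ncol(states)
  loss <- matrix(FALSE, st$nn, P)
  nonroot <- setdiff(seq_len(st$nn), st$root)
  if (root_present) {
    all0[st$root, ] <- FALSE
    for (v in nonroot) loss[v, ] <- all0[v, ] & !all0[st$parent[v], ]
  } else {
    total1 <- n1[st$root, ]
    t1 <- rep(total1, each = st$nn)
    full <- n1 == t1 & t1 > 0                 # contains every 1-leaf
    child_full <- matrix(FALSE, st$nn, P)
    for (v in nonroot) {
      p <- st$parent[v]
      child_full[p, ] <- child_full[p, ] | full[v, ]
    }
    is_mrca <- full & !child_full
    for (v in nonroot) {
      p <- st$parent[v]
      inside <- (n1[p, ] > 0L & n1[p, ] < total1) | is_mrca[p, ]
      loss[v, ] <- all0[v, ] & inside
    }
  }
  loss
}

## internal: encode a presence matrix into unique column patterns.
## Returns states (leaves x P, in `tip_order` row order), weights, and the
## per-gene pattern index.
compress_patterns <- function(matrix, tip_order) {
  miss <- setdiff(tip_order, matrix$species)
  extra <- setdiff(matrix$species, tip_order)
  if (length(miss) || length(extra))
    stop("species mismatch between tree and matrix; missing from matrix: {",
         paste(miss, collapse = ", "), "}; absent from tree: {",
         paste(extra, collapse = ", "), "}")
  s <- matrix$states[tip_order, , drop = FALSE]
  enc <- s
  enc[is.na(enc)] <- 2L
  key <- as.vector(3 ^ (seq_len(nrow(enc)) - 1) %*% enc)
  ui <- which(!duplicated(key))
  idx <- match(key, key[ui])
  list(states = s[, ui, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(ui))),
       index = idx)
}

#' Dollo fit of a single binary character
#'
#' Computes the minimum number of irreversible losses (1 -> 0) needed to
#' explain a character on a rooted tree, together with the branches
#' carrying those losses and the gain placement. Missing states (`NA` or
#' `"?"`) are resolved to whichever state minimizes the loss count.
#'
#' @param tree Rooted `phylo` (polytomies allowed, scored hard).
#' @param chr Named vector of states over the tree's leaves: values in
#'   {0, 1, NA} (or `"?"`).
#' @param root_present If `TRUE` (the default, appropriate when every gene
#'   existed in the ancestor of the sampled clade) the gain is fixed at the
#'   root; if `FALSE` a single gain is placed above the MRCA of the present
#'   leaves.
#' @return List with `losses` (integer), `loss_branches` (branch ids, see
#'   [branch_ids()]), and `gain_branch` (a branch id, `"root"`, or `NA`
#'   for a never-gained all-absent character under free gain).
#' @export
dollo_fit <- function(tree, chr, root_present = TRUE) {
  if (is.character(chr)) {
    chr[chr == "?"] <- NA
    chr <- stats::setNames(as.integer(chr), names(chr))
  }
  bad <- setdiff(names(chr), tree$tip.label)
  if (length(bad)) stop("character names not in tree: ", paste(bad, collapse = ", "))
  states <- matrix(NA_integer_, ape::Ntip(tree), 1)
  states[match(names(chr), tree$tip.label), 1] <- as.integer(chr)
  st <- tree_struct(tree)
  loss <- dollo_loss_matrix(st, states, root_present)[, 1]
  ids <- branch_ids(tree)
  loss_branches <- unname(ids[as.character(which(loss))])
  gain <- if (root_present) "root" else {
    cn <- node_counts(st, states)
    total1 <- cn$n1[st$root, 1]
    if (total1 == 0) NA_character_ else {
      full <- which(cn$n1[, 1] == total1)   # ancestors-or-equal of the MRCA
      mrca <- setdiff(full, st$parent[full])
      if (mrca == st$root) "root" else unname(ids[as.character(mrca)])
    }
  }
  list(losses = sum(loss), loss_branches = loss_branches, gain_branch = gain)
}

#' Total Dollo score of a tree for a presence matrix
#'
#' Sum over genes of the per-character minimum loss count. Invariant
#' (all-present) and all-missing characters contribute zero. Identical
#' gene columns are collapsed to unique patterns internally, so the cost
#' scales with the number of distinct patterns rather than genes.
#'
#' @inheritParams dollo_fit
#' @param matrix A [presence_matrix()] whose species equal the tree's
#'   leaves.
#' @return Total loss count (numeric).
#' @export
tree_score <- function(tree, matrix, root_present = TRUE) {
  cp <- compress_patterns(matrix, tree$tip.label)
  st <- tree_struct(tree)
  loss <- dollo_loss_matrix(st, cp$states, root_present)
  sum(colSums(loss) * cp$weights)
}

#' Per-gene Dollo score profile
#'
#' Decomposes the total Dollo score of a tree into per-gene loss counts,
#' the unit of resampling for the topology tests.
#'
#' @inheritParams tree_score
#' @return List with `tree` (the input), `per_gene` (named integer vector
#'   ordered as the matrix genes) and `total`.
#' @export
score_profile <- function(tree, matrix, root_present = TRUE) {
  cp <- compress_patterns(matrix, tree$tip.label)
  st <- tree_struct(tree)
  per_pattern <- colSums(dollo_loss_matrix(st, cp$states, root_present))
  per_gene <- stats::setNames(as.integer(per_pattern[cp$index]), matrix$genes)
  list(tree = tree, per_gene = per_gene, total = sum(per_gene))
}
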