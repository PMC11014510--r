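## Most-parsimonious tree inference under the Dollo criterion.
##
## Trees under construction are nested lists over taxon indices: a leaf is
## an integer (the species row in the matrix), an internal node a list of
## two subtrees. Complete trees are converted to ape phylo objects at the
## end. Gene columns are compressed to unique patterns once per taxon
## subset, so scoring cost is independent of the raw gene count.

## internal: flatten a nested binary tree into the struct consumed by
## dollo_loss_matrix(); leaf_rows maps leaf node numbers to species rows.
nested_struct <- function(tree) {
  leaves <- integer(0); parents <- list(); post <- integer(0)
  count_leaves <- function(x) if (is.list(x)) sum(vapply(x, count_leaves, 0L)) else 1L
  ntip <- count_leaves(tree)
  next_leaf <- 0L; next_int <- ntip + 1L
  parent <- integer(2L * ntip - 1L)
  leaf_rows <- integer(ntip)
  postorder <- integer(0)
  assign_num <- function(x) {
    if (is.list(x)) {
      me <- next_int; next_int <<- next_int + 1L
      for (ch in x) {
        cn <- assign_num(ch)
        parent[cn] <<- me
      }
      me
    } else {
      next_leaf <<- next_leaf + 1L
      leaf_rows[next_leaf] <<- x
      next_leaf
    }
  }
  root <- assign_num(tree)
  ## postorder: children before parents; internal nodes were numbered
  ## after their children, leaves are always ready, so ordering leaves
  ## first then internals ascending (excluding root) is a valid postorder
  ## ... except the root got the smallest internal number. Use depth-sorted
  ## order instead: process nodes by decreasing depth.
  depth <- integer(2L * ntip - 1L)
  for (v in seq_len(2L * ntip - 1L)) {
    d <- 0L; u <- v
    while (u != root) { u <- parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  ord <- setdiff(order(depth, decreasing = TRUE), root)
  list(ntip = ntip, nn = 2L * ntip - 1L, root = root, parent = parent,
       postorder = ord, leaf_rows = leaf_rows)
}

## internal: Dollo score of a nested tree. states is the full
## species x patterns matrix; weights the pattern multiplicities.
score_nested <- function(tree, states, weights, root_present = TRUE) {
  st <- nested_struct(tree)
  s <- states[st$leaf_rows, , drop = FALSE]
  loss <- dollo_loss_matrix(st, s, root_present)
  sum(colSums(loss) * weights)
}

## internal: all rooted trees obtained by inserting leaf x on every branch
## of `tree` (including above the root): 2k-1 placements for k leaves.
leaf_placements <- function(tree, x) {
  out <- list(list(tree, x))          # above the current root
  if (is.list(tree)) {
    for (i in seq_along(tree)) {
      for (sub in leaf_placements(tree[[i]], x)) {
        t2 <- tree
        t2[[i]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

## internal: remove a leaf (taxon index) from a nested tree
prune_leaf <- function(tree, x) {
  if (!is.list(tree)) return(if (identical(tree, x)) NULL else tree)
  kids <- lapply(tree, prune_leaf, x = x)
  kids <- kids[!vapply(kids, is.null, TRUE)]
  if (length(kids) == 1) kids[[1]] else kids
}

## internal: nested tree -> phylo with species labels
nested_to_phylo <- function(tree, labels) {
  rec <- function(x) if (is.list(x))
    paste0("(", paste(vapply(x, rec, ""), collapse = ","), ")") else labels[x]
  ape::read.tree(text = paste0(rec(tree), ";"))
}

## internal: compress a set of columns on a row subset
compress_rows <- function(states_full, rows, cols) {
  if (length(cols) == 0)
    return(list(states = states_full[, 0, drop = FALSE], weights = numeric(0)))
  enc <- states_full[rows, cols, drop = FALSE]
  enc[is.na(enc)] <- 2L
  key <- as.vector(3 ^ (seq_along(rows) - 1) %*% enc)
  ui <- which(!duplicated(key))
  idx <- match(key, key[ui])
  list(states = states_full[, cols[ui], drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(ui))))
}

## internal: lower-bound machinery for partial trees.
##
## With the gain forced at the root, the Dollo score of a partial tree is a
## valid lower bound only for characters with at least one present leaf in
## the taxon subset (restricting an optimal full solution to the subset then
## stays a valid root-present solution). A character with no present leaf in
## the subset contributes a topology-independent floor instead: 2 if it is
## absent in every species (any binary root has two all-absent children), 1
## if it has at least one observed absence, else 0.
level_bounds <- function(states_full, order) {
  n <- length(order)
  ngene <- ncol(states_full)
  has0 <- colSums(!is.na(states_full) & states_full == 0L) > 0
  any1 <- colSums(!is.na(states_full) & states_full == 1L) > 0
  all_obs0 <- colSums(is.na(states_full) | states_full == 0L) == nrow(states_full) &
    !any1 & has0 & colSums(is.na(states_full)) == 0
  floor_gene <- ifelse(all_obs0, 2, ifelse(has0, 1, 0))
  out <- vector("list", n)
  for (k in 2:n) {
    rows <- order[1:k]
    info <- colSums(!is.na(states_full[rows, , drop = FALSE]) &
                      states_full[rows, , drop = FALSE] == 1L) > 0
    cp <- compress_rows(states_full, rows, which(info))
    out[[k]] <- c(cp, list(const = sum(floor_gene[!info])))
  }
  out
}

## internal: partial-tree lower bound at level k
bound_nested <- function(tree, lb_k, root_present) {
  score_nested(tree, lb_k$states, lb_k$weights, root_present) + lb_k$const
}

## internal: greedy stepwise addition over a fixed taxon order; the last
## taxon is placed by true score (full_cp), earlier ones by the bound
greedy_addition <- function(order, lb, full_cp, root_present) {
  tree <- list(order[1], order[2])
  n <- length(order)
  for (k in seq_along(order)[-(1:2)]) {
    cand <- leaf_placements(tree, order[k])
    sc <- if (k == n)
      vapply(cand, score_nested, 0, states = full_cp$states,
             weights = full_cp$weights, root_present = root_present)
    else
      vapply(cand, bound_nested, 0, lb_k = lb[[k]], root_present = root_present)
    tree <- cand[[which.min(sc)]]
  }
  tree
}

## internal: assemble a SearchResult
search_result <- function(best_score, nested_best, labels, evaluated, mode) {
  trees <- lapply(nested_best, nested_to_phylo, labels = labels)
  canon <- vapply(trees, canonical_topology, "")
  keep <- !duplicated(canon)
  trees <- trees[keep][order(canon[keep])]
  structure(list(best_score = best_score, best_trees = trees,
                 evaluated = evaluated, mode = mode),
            class = "dollo_search")
}

#' @export
print.dollo_search <- function(x, ...) {
  cat(sprintf("Dollo %s search: best score %g, %d co-optimal tree(s), %d trees scored\n",
              x$mode, x$best_score, length(x$best_trees), x$evaluated))
  invisible(x)
}

#' Exact most-parsimonious Dollo trees by branch and bound
#'
#' Enumerates rooted binary topologies by stepwise taxon addition, pruning
#' any partial tree whose score already exceeds the incumbent: a character's
#' score on a leaf-induced subtree never exceeds its score on the full
#' tree, so partial scores are valid lower bounds. The initial incumbent
#' comes from greedy stepwise addition, and taxa are added in decreasing
#' order of their effect on the greedy tree's score (tighter early bounds).
#' All co-optimal trees are returned, sorted by canonical topology; the
#' first is the headline tree.
#'
#' @param matrix A [presence_matrix()].
#' @param max_exact_taxa Refuse instances larger than this (default 12).
#' @param seed Unused by the exact search (kept for interface symmetry).
#' @param root_present Fix the gain at the root (default `TRUE`).
#' @return A `dollo_search` result: `best_score`, `best_trees` (list of
#'   `phylo`), `evaluated`, `mode = "exact"`.
#' @export
branch_and_bound <- function(matrix, max_exact_taxa = 12, seed = 1,
                             root_present = TRUE) {
  n <- length(matrix$species)
  if (n < 3) stop("need at least 3 species")
  if (n > max_exact_taxa)
    stop("n = ", n, " exceeds max_exact_taxa = ", max_exact_taxa,
         "; use heuristic_search()")
  states <- matrix$states
  full_cp <- compress_patterns(matrix, matrix$species)
  true_score <- function(tr) score_nested(tr, full_cp$states, full_cp$weights,
                                          root_present)
  ## addition order: exclusion impact on the greedy tree
  lb0 <- level_bounds(states, seq_len(n))
  g0 <- greedy_addition(seq_len(n), lb0, full_cp, root_present)
  full_sc <- true_score(g0)
  impact <- vapply(seq_len(n), function(t) {
    pruned <- prune_leaf(g0, t)
    rows <- setdiff(seq_len(n), t)
    cp <- compress_rows(states, rows, seq_len(ncol(states)))
    full_sc - score_nested(pruned, cp$states, cp$weights, root_present)
  }, 0)
  ord <- order(impact, decreasing = TRUE)
  lb <- level_bounds(states, ord)
  greedy <- greedy_addition(ord, lb, full_cp, root_present)
  incumbent <- true_score(greedy)
  best <- list(greedy)
  evaluated <- 0L
  recurse <- function(tree, k) {
    for (cand in leaf_placements(tree, ord[k])) {
      evaluated <<- evaluated + 1L
      if (k == n) {
        sc <- true_score(cand)
        if (sc < incumbent) { incumbent <<- sc; best <<- list(cand) }
        else if (sc == incumbent) best <<- c(best, list(cand))
      } else {
        if (bound_nested(cand, lb[[k]], root_present) > incumbent) next
        recurse(cand, k + 1L)
      }
    }
  }
  recurse(list(ord[1], ord[2]), 3L)
  ## the greedy seed may have been superseded; rescore and filter
  best <- best[vapply(best, true_score, 0) == incumbent]
  search_result(incumbent, best, matrix$species, evaluated, "exact")
}

#' Exhaustive Dollo search (oracle-grade, tiny instances only)
#'
#' Scores every rooted binary topology by unpruned recursive enumeration.
#' Exponential ((2n-3)!! topologies); intended for cross-checks at n <= 7.
#'
#' @inheritParams branch_and_bound
#' @return A `dollo_search` result, `mode = "exact"`.
#' @export
exhaustive_search <- function(matrix, root_present = TRUE) {
  n <- length(matrix$species)
  if (n < 3) stop("need at least 3 species")
  if (n > 8) stop("exhaustive enumeration is limited to n <= 8")
  trees <- list(list(1L, 2L))
  for (k in 3:n)
    trees <- unlist(lapply(trees, leaf_placements, x = k), recursive = FALSE)
  cp <- compress_patterns(matrix, matrix$species)
  sc <- vapply(trees, score_nested, 0, states = cp$states,
               weights = cp$weights, root_present = root_present)
  best_score <- min(sc)
  search_result(best_score, trees[sc == best_score], matrix$species,
                length(trees), "exact")
}

## internal: all rooted NNI neighbors of a nested binary tree
nni_neighbors <- function(tree) {
  out <- list()
  rec <- function(node, path) {
    if (!is.list(node)) return(invisible())
    for (i in 1:2) {
      ch <- node[[i]]
      if (is.list(ch)) {
        sib <- node[[3 - i]]
        ## swap sibling with each child of ch
        for (j in 1:2) {
          new_ch <- ch; new_ch[[j]] <- sib
          new_node <- list(new_ch, ch[[j]])
          t2 <- replace_at(tree, path, new_node)
          out[[length(out) + 1L]] <<- t2
        }
      }
      rec(ch, c(path, i))
    }
  }
  rec(tree, integer(0))
  out
}

## internal: replace the subtree at `path` (sequence of child indices)
replace_at <- function(tree, path, value) {
  if (length(path) == 0) return(value)
  tree[[path[1]]] <- replace_at(tree[[path[1]]], path[-1], value)
  tree
}

#' Heuristic Dollo search: random addition plus NNI hill climbing
#'
#' Each start draws a random taxon addition order, builds a greedy
#' stepwise-addition tree, then applies nearest-neighbor-interchange moves
#' while any strictly improves the score. Deterministic given `seed`.
#'
#' @inheritParams branch_and_bound
#' @param n_starts Number of random-addition starts (default 10).
#' @return A `dollo_search` result, `mode = "heuristic"`, retaining all
#'   co-optimal trees found across starts.
#' @export
heuristic_search <- function(matrix, n_starts = 10, seed = 1,
                             root_present = TRUE) {
  n <- length(matrix$species)
  if (n < 4) stop("need at least 4 species")
  states <- matrix$states
  cp <- compress_patterns(matrix, matrix$species)
  evaluated <- 0L
  score1 <- function(tr) {
    evaluated <<- evaluated + 1L
    score_nested(tr, cp$states, cp$weights, root_present)
  }
  best_score <- Inf; best <- list()
  rng <- make_rng(seed)
  for (s in seq_len(n_starts)) {
    ord <- sample_int(rng, n, n)
    tree <- greedy_addition(ord, level_bounds(states, ord), cp, root_present)
    sc <- score1(tree)
    repeat {
      nb <- nni_neighbors(tree)
      nsc <- vapply(nb, score1, 0)
      if (length(nsc) == 0 || min(nsc) >= sc) break
      i <- which.min(nsc)
      tree <- nb[[i]]; sc <- nsc[i]
    }
    if (sc < best_score) { best_score <- sc; best <- list(tree) }
    else if (sc == best_score) best <- c(best, list(tree))
  }
  search_result(best_score, best, matrix$species, evaluated, "heuristic")
}

#' Bootstrap majority-rule consensus of Dollo trees
#'
#' Resamples gene columns with replacement (the character-resampling
#' analogue of sequence bootstrapping), reruns the configured search on
#' each replicate, takes the headline (first canonical) best tree, and
#' assembles a majority-rule consensus from clade frequencies.
#'
#' @inheritParams branch_and_bound
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param threshold Clade retention threshold as a proportion (default 0.5,
#'   strict majority; must be in [0.5, 1)).
#' @param search `"exact"` (branch and bound) or `"heuristic"`.
#' @param n_starts Starts per replicate for the heuristic search.
#' @return List of class `dollo_consensus`: `tree` (consensus `phylo` with
#'   support percentages as node labels), `support` (data frame of clade
#'   ids and support percentages for all sampled clades), `n_reps`.
#' @export
bootstrap_consensus <- function(matrix, n_reps = 100, threshold = 0.5,
                                seed = 1, search = c("exact", "heuristic"),
                                n_starts = 5, max_exact_taxa = 12,
                                root_present = TRUE) {
  search <- match.arg(search)
  stopifnot(n_reps >= 1, threshold >= 0.5, threshold < 1)
  n <- length(matrix$species)
  ngene <- length(matrix$genes)
  rng <- make_rng(seed)
  ## resample over a canonical (pattern-sorted) column order so supports do
  ## not depend on the order genes happen to appear in the matrix
  enc <- matrix$states; enc[is.na(enc)] <- 2L
  canon <- order(as.vector(3 ^ (seq_len(n) - 1) %*% enc))
  states_c <- matrix$states[, canon, drop = FALSE]
  clade_count <- new.env(parent = emptyenv())
  for (b in seq_len(n_reps)) {
    cols <- sample_int(rng, ngene, ngene, replace = TRUE)
    mb <- presence_matrix(states_c[, cols, drop = FALSE],
                          species = matrix$species,
                          genes = paste0("bs", seq_len(ngene)))
    res <- if (search == "exact")
      branch_and_bound(mb, max_exact_taxa = max_exact_taxa,
                       root_present = root_present)
    else heuristic_search(mb, n_starts = n_starts, seed = derive_seed(rng),
                          root_present = root_present)
    tr <- res$best_trees[[1]]
    for (cl in tree_clades(tr)) {
      clade_count[[cl]] <- (if (is.null(clade_count[[cl]])) 0L else clade_count[[cl]]) + 1L
    }
  }
  ids <- ls(clade_count)
  supp <- vapply(ids, function(k) clade_count[[k]], 0L) * 100 / n_reps
  tab <- data.frame(clade = ids, support = unname(supp),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$support, tab$clade), , drop = FALSE]
  rownames(tab) <- NULL
  keep <- tab[tab$support > threshold * 100, , drop = FALSE]
  ## strict-majority clades are pairwise compatible; verify anyway
  sets <- lapply(strsplit(keep$clade, "|", fixed = TRUE), sort)
  ok <- rep(TRUE, length(sets))
  accepted <- list()
  for (i in seq_along(sets)) {
    comp <- all(vapply(accepted, function(a) {
      ov <- length(intersect(a, sets[[i]]))
      ov == 0 || ov == length(a) || ov == length(sets[[i]])
    }, TRUE))
    if (comp) accepted <- c(accepted, sets[i]) else ok[i] <- FALSE
  }
  keep <- keep[ok, , drop = FALSE]
  cons <- clades_to_tree(accepted[order(-vapply(accepted, length, 0L))],
                         matrix$species,
                         stats::setNames(keep$support, keep$clade))
  structure(list(tree = cons, support = tab, n_reps = n_reps),
            class = "dollo_consensus")
}

#' @export
print.dollo_consensus <- function(x, ...) {
  cat(sprintf("Bootstrap consensus (%d replicates): %d clades above threshold\n",
              x$n_reps, sum(!is.na(x$tree$node.label) & nzchar(x$tree$node.label)) ))
  invisible(x)
}

## internal: non-trivial clades (proper, size >= 2) of a rooted tree as
## branch-id strings
tree_clades <- function(tree) {
  ids <- branch_ids(tree)
  ids <- ids[as.integer(names(ids)) > ape::Ntip(tree)]
  unname(ids)
}

## internal: build a (possibly multifurcating) rooted tree from a nested
## family of clades; `supports` maps clade id -> percentage
clades_to_tree <- function(clades, taxa, supports = NULL) {
  nodes <- c(list(sort(taxa)), clades)   # root first, then by size desc
  lab <- function(s) paste(s, collapse = "|")
  build <- function(i) {
    members <- nodes[[i]]
    ## direct children among clades: maximal proper subsets
    child_idx <- Filter(function(j) {
      j != i && all(nodes[[j]] %in% members) && length(nodes[[j]]) < length(members) &&
        !any(vapply(seq_along(nodes), function(k)
          k != i && k != j && all(nodes[[j]] %in% nodes[[k]]) &&
            length(nodes[[k]]) < length(members) && all(nodes[[k]] %in% members),
          TRUE))
    }, seq_along(nodes))
    covered <- unlist(nodes[child_idx])
    singles <- setdiff(members, covered)
    parts <- c(vapply(child_idx, build, ""), singles)
    sup <- if (!is.null(supports) && i > 1) {
      v <- supports[[lab(nodes[[i]])]]
      if (is.null(v) || is.na(v)) "" else format(round(v, 1))
    } else ""
    paste0("(", paste(parts, collapse = ","), ")", sup)
  }
  ape::read.tree(text = paste0(build(1), ";"))
}
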