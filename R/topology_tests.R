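## Parsimony variant of the Shimodaira-Hasegawa branch test.
##
## Support for each branch of the most-parsimonious (MP) tree is assessed
## by collapsing the branch to a polytomy, recomputing the per-gene Dollo
## scores, and testing whether the collapsed tree is significantly worse.
## Two p-values are reported per comparison: a Templeton (winning-sites)
## Wilcoxon signed-rank test on the per-gene score differences, and a RELL
## bootstrap of the per-gene differences with SH-style centering.

## internal: two-sided Wilcoxon signed-rank p on nonzero differences.
## Exact enumeration of the 2^m sign assignments when m <= exact_limit
## (valid with ties); otherwise normal approximation with the tie-robust
## variance sum(r_i^2)/4. Under H0 the statistic is symmetric about
## m(m+1)/4 for any tie pattern, so the two-sided p is P(|W-mu|>=|w-mu|).
templeton_p <- function(d, exact_limit = 12) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (m <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    ws <- as.vector(signs %*% r)
    mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    2 * stats::pnorm(-abs(w - mu) / sigma)
  }
}

#' Paired topology test on two Dollo score profiles
#'
#' Compares a reference tree (normally the MP tree) with an alternative
#' over the same presence matrix using the per-gene score differences
#' `d_i = alt_i - ref_i`. Reports the Templeton signed-rank p (two-sided)
#' and a one-sided RELL resampling p: gene contributions are resampled with
#' replacement `n_resamples` times, sums are centered at the observed sum
#' (the SH convention), and p is the add-one-smoothed fraction of centered
#' sums at or above the observed difference.
#'
#' @param ref,alt Score profiles from [score_profile()] over identical gene
#'   lists.
#' @param n_resamples RELL bootstrap replicates (default 10000).
#' @param seed RNG seed for the resampling.
#' @param label Comparison label carried into the result.
#' @return Data frame row: `comparison`, `delta`, `p_templeton`, `p_rell`,
#'   `n_resamples`, `seed`.
#' @export
paired_topology_test <- function(ref, alt, n_resamples = 10000, seed = 1,
                                 label = "alt_vs_ref") {
  if (!identical(names(ref$per_gene), names(alt$per_gene)))
    stop("profiles are over different gene lists")
  d <- as.numeric(alt$per_gene - ref$per_gene)
  delta <- sum(d)
  rng <- make_rng(seed)
  ngene <- length(d)
  exceed <- 0L
  block <- 2000L
  done <- 0L
  while (done < n_resamples) {
    b <- min(block, n_resamples - done)
    idx <- matrix(sample_int(rng, ngene, ngene * b, replace = TRUE), ngene, b)
    sums <- colSums(matrix(d[idx], ngene, b))
    exceed <- exceed + sum(sums - delta >= delta)
    done <- done + b
  }
  data.frame(comparison = label, delta = delta,
             p_templeton = templeton_p(d),
             p_rell = (exceed + 1) / (n_resamples + 1),
             n_resamples = n_resamples, seed = seed,
             stringsAsFactors = FALSE)
}

#' SH-style scan over the internal branches of an MP tree
#'
#' For every collapsible internal branch, collapses it to a polytomy,
#' recomputes the Dollo score profile, and runs [paired_topology_test()]
#' against the MP profile. Collapsing a branch can only raise the Dollo
#' score, so every `delta` is nonnegative. When the root is bifurcating its
#' two child branches describe the same bipartition; that split is tested
#' once, using the better-scoring (minimum-delta) of the two collapses.
#'
#' @param mp_tree Rooted `phylo`, normally the headline MP tree.
#' @param matrix A [presence_matrix()].
#' @inheritParams paired_topology_test
#' @param root_present Passed to the Dollo scoring.
#' @return Data frame, one row per tested branch (comparison = branch id).
#' @export
branch_sh_scan <- function(mp_tree, matrix, n_resamples = 10000, seed = 1,
                           root_present = TRUE) {
  ref <- score_profile(mp_tree, matrix, root_present)
  ids <- branch_ids(mp_tree)
  internal <- as.integer(names(ids)) > ape::Ntip(mp_tree)
  cand <- ids[internal]
  if (length(cand) == 0) stop("tree has no collapsible internal branch")
  kids_root <- phylo_children(mp_tree)[[phylo_root(mp_tree)]]
  root_pair <- NULL
  if (length(kids_root) == 2 && all(kids_root > ape::Ntip(mp_tree)))
    root_pair <- unname(ids[as.character(kids_root)])
  rng <- make_rng(seed)
  profiles <- lapply(cand, function(b)
    score_profile(collapse_branch(mp_tree, b), matrix, root_present))
  names(profiles) <- cand
  if (!is.null(root_pair)) {
    tot <- vapply(profiles[root_pair], `[[`, 0, "total")
    drop_id <- root_pair[which.max(tot)]
    profiles <- profiles[names(profiles) != drop_id]
  } else if (length(kids_root) == 2) {
    ## one root child is a leaf: its sibling's branch repeats the root
    ## split of the remaining subtree only when that sibling is internal;
    ## nothing to merge here.
  }
  out <- do.call(rbind, lapply(names(profiles), function(b)
    paired_topology_test(ref, profiles[[b]], n_resamples = n_resamples,
                         seed = derive_seed(rng), label = b)))
  rownames(out) <- NULL
  out
}
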