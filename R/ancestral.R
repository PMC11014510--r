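## Dollo ancestral reconstruction of gene losses on a fixed species tree.

#' Reconstruct ancestral gene losses on a fixed species tree
#'
#' Places every gene's losses on the tree under Dollo parsimony with the
#' gene enforced present in the common ancestor, and tallies losses per
#' branch. Genes absent from every species are reference-private artifacts
#' (present only in the annotation reference): under a forced-present root
#' they incur one loss per root child, so they are tallied but also
#' reported separately in `all_absent_genes`.
#'
#' @param tree Rooted `phylo`; polytomies allowed (e.g. an unresolved
#'   Paenungulata).
#' @param matrix A [presence_matrix()] with species equal to the tree's
#'   leaves.
#' @return Object of class `loss_reconstruction`: `tree`, `per_gene` (named
#'   list of loss branch ids), `branch_counts` (named integer vector over
#'   all branch ids), `gene_branch` (long-format data frame gene/branch),
#'   `all_absent_genes`, `total_losses`.
#' @export
reconstruct_losses <- function(tree, matrix) {
  cp <- compress_patterns(matrix, tree$tip.label)
  st <- tree_struct(tree)
  loss <- dollo_loss_matrix(st, cp$states, root_present = TRUE)
  ids <- branch_ids(tree)
  id_of_node <- rep(NA_character_, st$nn)
  id_of_node[as.integer(names(ids))] <- ids
  pat_branches <- apply(loss, 2, function(col) id_of_node[which(col)],
                        simplify = FALSE)
  per_gene <- pat_branches[cp$index]
  names(per_gene) <- matrix$genes
  counts_pat <- loss %*% cp$weights
  branch_counts <- stats::setNames(as.integer(counts_pat[as.integer(names(ids))]),
                                   unname(ids))
  nl <- lengths(per_gene)
  gene_branch <- data.frame(gene = rep(matrix$genes, nl),
                            branch = unlist(per_gene, use.names = FALSE),
                            stringsAsFactors = FALSE)
  obs <- !is.na(matrix$states)
  all_absent <- matrix$genes[colSums(obs & matrix$states == 1L) == 0 &
                               colSums(obs) > 0]
  structure(list(tree = tree, per_gene = per_gene,
                 branch_counts = branch_counts, gene_branch = gene_branch,
                 all_absent_genes = all_absent,
                 total_losses = sum(branch_counts)),
            class = "loss_reconstruction")
}

#' @export
print.loss_reconstruction <- function(x, ...) {
  cat(sprintf("loss_reconstruction: %d losses over %d branches (%d genes, %d all-absent)\n",
              x$total_losses, sum(x$branch_counts > 0), length(x$per_gene),
              length(x$all_absent_genes)))
  invisible(x)
}

#' Regress per-branch loss counts on branch lengths
#'
#' Tests whether gene losses accumulate clock-like (count proportional to
#' branch duration in millions of years) and flags branches losing far more
#' or fewer genes than their length predicts. Pearson correlation with the
#' two-sided t test `r * sqrt((n-2)/(1-r^2))` on n-2 df; ordinary least
#' squares fit; outliers are branches with |standardized residual| > 2 by
#' default (the threshold is a reporting choice, not a hypothesis test).
#'
#' @param rec A [reconstruct_losses()] result.
#' @param lengths Named numeric vector, branch id -> length in My. Defaults
#'   to the reconstruction tree's own branch lengths.
#' @param include_terminal Include terminal branches (default `TRUE`).
#' @param outlier_z Standardized-residual threshold (default 2).
#' @return Object of class `branch_regression`: `table` (branch, length,
#'   count, fitted, std_residual, outlier), `r`, `r2`, `p_value`,
#'   `outlier_branches`.
#' @export
branch_regression <- function(rec, lengths = NULL, include_terminal = TRUE,
                              outlier_z = 2) {
  if (is.null(lengths)) lengths <- branch_lengths(rec$tree)
  branches <- names(rec$branch_counts)
  if (!include_terminal) {
    terminal <- !grepl("|", branches, fixed = TRUE)
    branches <- branches[!terminal]
  }
  missing_len <- setdiff(branches, names(lengths))
  if (length(missing_len))
    stop("no length for branches: ", paste(missing_len, collapse = ", "))
  x <- as.numeric(lengths[branches])
  y <- as.numeric(rec$branch_counts[branches])
  n <- length(x)
  if (n < 3) stop("need at least 3 branches")
  if (stats::var(x) == 0) stop("branch lengths have zero variance")
  r <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)
  p <- if (is.na(r) || abs(r) == 1) {
    if (is.na(r)) NA_real_ else 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  if (is.na(r)) { r <- 0; p <- 1 }   # constant counts: no association
  fit <- stats::lm(y ~ x)
  z <- stats::rstandard(fit)
  z[!is.finite(z)] <- 0   # perfect fit: residual sd 0
  out_flag <- abs(z) > outlier_z
  tab <- data.frame(branch = branches, length = x, count = y,
                    fitted = stats::fitted(fit), std_residual = as.numeric(z),
                    outlier = out_flag, stringsAsFactors = FALSE)
  structure(list(table = tab, r = r, r2 = r^2, p_value = p,
                 outlier_branches = branches[out_flag]),
            class = "branch_regression")
}

#' @export
print.branch_regression <- function(x, ...) {
  cat(sprintf("branch_regression: r^2 = %.3f, P = %.3g, %d outlier branch(es)\n",
              x$r2, x$p_value, length(x$outlier_branches)))
  if (length(x$outlier_branches))
    cat("  outliers:", paste(substr(x$outlier_branches, 1, 60), collapse = "; "), "\n")
  invisible(x)
}

#' Foreground gene set from a loss reconstruction
#'
#' The enrichment foreground: genes lost on at least one internal branch
#' (losses shared by two or more species, hence unlikely to be single
#' assembly artifacts), or all lost genes when `internal_only = FALSE`.
#'
#' @param rec A [reconstruct_losses()] result.
#' @param internal_only Restrict to internal (non-terminal) loss branches.
#' @return Character vector of gene ids (deduplicated).
#' @export
foreground_from_reconstruction <- function(rec, internal_only = TRUE) {
  keep <- vapply(rec$per_gene, function(br) {
    if (length(br) == 0) return(FALSE)
    if (!internal_only) return(TRUE)
    any(grepl("|", br, fixed = TRUE))
  }, TRUE)
  names(rec$per_gene)[keep]
}
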