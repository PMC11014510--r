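## Exploratory structure of the presence/absence matrix: do species group
## by phylogenetic relatedness (shared derived losses) or randomly
## (technical noise)? Distances on the binary rows, soft membership by
## distance-based fuzzy c-means, ordination by classical MDS with k-means
## partitioning, and cluster-number diagnostics.

#' Pairwise species distances on a presence matrix
#'
#' For binary rows the Manhattan distance is the count of genes with
#' differing states (cluster membership downstream is robust to the
#' metric choice). Missing states propagate as in [stats::dist()]
#' (pairwise-complete scaling).
#'
#' @param matrix A [presence_matrix()].
#' @param metric `"manhattan"`, `"euclidean"` or `"jaccard"` (asymmetric
#'   binary: mismatches over positions where either species has the gene).
#' @return A `dist` object labeled by species.
#' @export
pairwise_distances <- function(matrix, metric = c("manhattan", "euclidean", "jaccard")) {
  metric <- match.arg(metric)
  method <- c(manhattan = "manhattan", euclidean = "euclidean",
              jaccard = "binary")[[metric]]
  stats::dist(matrix$states, method = method)
}

#' Distance-based fuzzy c-means clustering
#'
#' The fuzzy criterion of Kaufman & Rousseeuw (the `fanny` objective):
#' minimize `sum_v (sum_ij u_iv^m u_jv^m d_ij) / (2 sum_j u_jv^m)` over
#' membership rows summing to 1. Memberships are updated by the standard
#' alternating rule on per-object cluster dissimilarities; a step-halving
#' safeguard keeps the objective non-increasing at every iteration.
#' The fuzzifier `m` must exceed 1: at `m = 1` the update degenerates to
#' hard assignment (use k-means on an ordination instead).
#'
#' @param D A `dist` or symmetric distance matrix with labels.
#' @param K Number of clusters, `2 <= K < n`.
#' @param m Fuzzifier exponent (> 1, default 1.2).
#' @param tol Stop when the objective improves by less than this.
#' @param max_iter Iteration cap.
#' @param seed Seed for the random membership initializations.
#' @param n_starts Random restarts; the run with the lowest final objective
#'   wins (ties broken by lowest restart index).
#' @return Object of class `fuzzy_model`: `K`, `m`, `U` (species x K
#'   memberships), `objective` (final value), `objective_trace`,
#'   `iterations`, `hard` (argmax labels).
#' @export
fuzzy_cluster <- function(D, K, m = 1.2, tol = 1e-9, max_iter = 500, seed = 1,
                          n_starts = 5) {
  rng <- make_rng(seed)
  ## first start: crisp k-means partition of the classical-MDS embedding
  ## softened into memberships; remaining starts are random
  d0 <- as.matrix(D)
  init <- tryCatch({
    X <- suppressWarnings(stats::cmdscale(stats::as.dist(d0),
                                          k = min(K, nrow(d0) - 1)))
    km <- kmeans_multistart(X, K, n_starts = 5, seed = derive_seed(rng))
    U0 <- matrix((1 - 0.9) / (K - 1), nrow(d0), K)
    U0[cbind(seq_len(nrow(d0)), km$cluster)] <- 0.9
    U0
  }, error = function(e) NULL)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- fuzzy_cluster_once(D, K, m, tol, max_iter, rng,
                              U_init = if (s == 1) init else NULL)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

fuzzy_cluster_once <- function(D, K, m, tol, max_iter, rng, U_init = NULL) {
  d <- as.matrix(D)
  n <- nrow(d)
  if (K < 2 || K >= n) stop("need 2 <= K < n")
  if (m <= 1) stop("fuzzifier m must be > 1 (m = 1 is hard assignment; use k-means)")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  U <- if (is.null(U_init))
    matrix(runif_rng(rng, n * K, min = 0.01, max = 1), n, K)
  else U_init
  U <- U / rowSums(U)
  objective <- function(U) {
    Um <- U^m
    sum(vapply(seq_len(K), function(v) {
      num <- as.numeric(t(Um[, v]) %*% d %*% Um[, v])
      den <- 2 * sum(Um[, v])
      if (den == 0) 0 else num / den
    }, 0))
  }
  obj <- objective(U)
  trace <- obj
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Um <- U^m
    ## per-object dissimilarity to each cluster:
    ## a_iv = (sum_j u_jv^m d_ij)/e_v - (sum_jl u_jv^m u_lv^m d_jl)/(2 e_v^2)
    e <- colSums(Um)
    dU <- d %*% Um                      # n x K
    within <- vapply(seq_len(K), function(v)
      as.numeric(t(Um[, v]) %*% d %*% Um[, v]), 0)
    a <- sweep(dU, 2, e, "/") - matrix(rep(within / (2 * e^2), each = n), n, K)
    a <- pmax(a, 1e-12)
    Unew <- a^(-1 / (m - 1))
    Unew <- Unew / rowSums(Unew)
    ## step-halving safeguard: the closed-form update is not guaranteed
    ## monotone for every m; back off toward the previous memberships
    step <- 1
    repeat {
      Utry <- (1 - step) * U + step * Unew
      otry <- objective(Utry)
      if (otry <= obj + 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    improved <- obj - otry
    if (otry <= obj) { U <- Utry; obj <- otry }
    trace <- c(trace, obj)
    if (improved < tol) break
  }
  dimnames(U) <- list(labels, paste0("cluster", seq_len(K)))
  hard <- stats::setNames(max.col(U, ties.method = "first"), labels)
  structure(list(K = K, m = m, U = U, objective = obj,
                 objective_trace = trace, iterations = it, hard = hard),
            class = "fuzzy_model")
}

#' @export
print.fuzzy_model <- function(x, ...) {
  cat(sprintf("fuzzy_model: K = %d, m = %.2f, objective %.4f after %d iterations\n",
              x$K, x$m, x$objective, x$iterations))
  invisible(x)
}

## internal: k-means with seeded multi-start; best total within-SS wins,
## ties broken by lowest restart index
kmeans_multistart <- function(X, K, n_starts = 10, seed = 1) {
  rng <- make_rng(seed)
  key <- apply(X, 1, paste, collapse = ",")
  ndistinct <- length(unique(key))
  if (ndistinct <= K) {   # k-means cannot seed K centers; partition exactly
    cl <- match(key, unique(key))
    wss <- sum(vapply(unique(cl), function(g) {
      Xi <- X[cl == g, , drop = FALSE]
      sum(sweep(Xi, 2, colMeans(Xi))^2)
    }, 0))
    return(list(cluster = cl, tot.withinss = wss))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    km <- with_rng(rng, stats::kmeans(X, centers = min(K, nrow(X)),
                                      nstart = 1, iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Classical MDS ordination with k-means partitioning
#'
#' Torgerson's metric MDS: double-center `-D^2/2`, eigendecompose, keep the
#' top positive axes (exact for distances that are Euclidean in `dims`
#' dimensions), then partition the reduced coordinates with seeded
#' multi-start k-means.
#'
#' @param D A `dist` or symmetric distance matrix with labels.
#' @param dims Number of ordination axes requested (default 4).
#' @param K Number of k-means clusters (default 4).
#' @param seed Seed controlling the k-means restarts.
#' @param n_starts k-means restarts (default 10).
#' @return List of class `mds_partition`: `coordinates` (species x axes),
#'   `eigenvalues`, `dims` (axes actually returned), `cluster` (named hard
#'   labels), `withinss`.
#' @export
reduce_and_partition <- function(D, dims = 4, K = 4, seed = 1, n_starts = 10) {
  d <- stats::as.dist(D)
  n <- attr(d, "Size")
  if (dims < 1) stop("dims must be >= 1")
  if (K < 1) stop("K must be >= 1")
  dims_req <- min(dims, n - 1)
  mds <- stats::cmdscale(d, k = dims_req, eig = TRUE)
  pos <- sum(mds$eig > sqrt(.Machine$double.eps) * max(abs(mds$eig)))
  if (pos < dims_req)
    warning("only ", pos, " positive eigenvalues; returning ", pos, " axes")
  keep <- min(dims_req, max(pos, 1))
  X <- if (ncol(mds$points) == 0) {   # fully degenerate: identical points
    matrix(0, n, 1, dimnames = list(attr(d, "Labels"), NULL))
  } else mds$points[, seq_len(min(keep, ncol(mds$points))), drop = FALSE]
  keep <- ncol(X)
  km <- kmeans_multistart(X, K, n_starts = n_starts, seed = seed)
  structure(list(coordinates = X, eigenvalues = mds$eig, dims = keep,
                 cluster = stats::setNames(km$cluster, rownames(X)),
                 withinss = km$tot.withinss),
            class = "mds_partition")
}

#' Cluster-number diagnostics: elbow and stability
#'
#' For each K in `K_range`, partitions the ordination with k-means and
#' reports the total within-cluster sum of squares (for the elbow rule:
#' the optimal K sits where the slope turns from steep to shallow) and the
#' adjusted Rand index between the K and K-1 partitions (a scalar stability
#' summary: low ARI flags cluster numbers where groupings reshuffle).
#'
#' @param D Distance matrix or `dist`.
#' @param K_range Integer vector of cluster numbers (default 2:10).
#' @param dims Ordination axes used throughout (default 4).
#' @param seed Seed for the k-means restarts.
#' @return Data frame: `K`, `withinss`, `ari_vs_prev` (NA for the first K).
#' @export
cluster_diagnostics <- function(D, K_range = 2:10, dims = 4, seed = 1) {
  n <- attr(stats::as.dist(D), "Size")
  K_range <- sort(unique(as.integer(K_range)))
  if (any(K_range < 2) || any(K_range > n - 1))
    stop("K_range must lie within [2, n-1]")
  rng <- make_rng(seed)
  parts <- list(); wss <- numeric(length(K_range))
  for (i in seq_along(K_range)) {
    rp <- reduce_and_partition(D, dims = dims, K = K_range[i],
                               seed = derive_seed(rng))
    parts[[i]] <- rp$cluster
    wss[i] <- rp$withinss
  }
  ari <- c(NA_real_, vapply(seq_along(K_range)[-1], function(i)
    adjusted_rand_index(parts[[i - 1]], parts[[i]]), 0))
  data.frame(K = K_range, withinss = wss, ari_vs_prev = ari)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects:
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length (paired by position).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (nij - expected) / (mx - expected)
}
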