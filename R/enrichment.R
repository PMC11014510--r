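## Hypergeometric over-representation analysis of lost genes.

#' Read a gene-set collection in GMT format
#'
#' One set per line: term id, description, then one or more member genes,
#' tab-separated. Duplicate genes within a set are collapsed; duplicate
#' term ids are an error.
#'
#' @param x Character vector of lines, or a path to a GMT file.
#' @return A `gene_set_collection`: named list of sets, each
#'   `list(description, genes)`.
#' @export
read_gmt <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(parts, function(p)
    list(description = p[2], genes = unique(p[-(1:2)])))
  names(sets) <- ids
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- vapply(x, function(s) length(s$genes), 0L)
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), min(sz), max(sz)))
  invisible(x)
}

## internal: log-space hypergeometric upper tail P(X >= k) for X ~
## Hypergeometric(N, K, n), by log-sum-exp over the tail terms. Stable for
## the large-N backgrounds of genome-wide ORA.
log_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(0)  # log(1)
  jmax <- min(K, n)
  if (k > jmax) return(-Inf)
  j <- k:jmax
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(lt)
  mx + log(sum(exp(lt - mx)))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the foreground within the
#' background universe. Sets are first restricted to the background, then
#' size-filtered on the restricted size K; the upper-tail hypergeometric p
#' is computed in log space and Benjamini-Hochberg adjusted across all
#' tested sets.
#'
#' @param foreground Character vector of genes of interest (must be a
#'   subset of `background`).
#' @param background Character vector: the gene universe.
#' @param sets A [read_gmt()] collection.
#' @param min_size,max_size Bounds on the background-restricted set size K
#'   (defaults 10 and 200, sized for large foregrounds).
#' @param blacklist Optional patterns removed from foreground and
#'   background before testing (see [filter_blacklist()]), so the universe
#'   size N matches the tested genes.
#' @return Data frame sorted by p: `term`, `description`, `k` (foreground
#'   hits), `K` (background hits), `n`, `N`, `ratio` ((k/n)/(K/N)), `p`,
#'   `q` (BH).
#' @export
ora <- function(foreground, background, sets, min_size = 10, max_size = 200,
                blacklist = NULL) {
  if (min_size > max_size) stop("min_size > max_size")
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(blacklist)) {
    drop_rx <- vapply(blacklist, utils::glob2rx, "")
    hit <- function(g) Reduce(`|`, lapply(drop_rx, grepl, x = g))
    background <- background[!hit(background)]
    foreground <- foreground[!hit(foreground)]
  }
  stray <- setdiff(foreground, background)
  if (length(stray))
    stop("foreground genes not in background: ",
         paste(utils::head(stray, 10), collapse = ", "),
         if (length(stray) > 10) " ..." else "")
  if (length(foreground) == 0) stop("empty foreground")
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(names(sets), function(id) {
    g <- intersect(sets[[id]]$genes, background)
    K <- length(g)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(g, foreground))
    data.frame(term = id, description = sets[[id]]$description,
               k = k, K = K, n = n, N = N,
               ratio = (k / n) / (K / N),
               p = exp(log_hyper_tail(k, K, n, N)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), ratio = numeric(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Affinity-propagation redundancy reduction of enriched terms
#'
#' Overlapping enriched terms (e.g. nested pathway annotations) are grouped
#' by affinity propagation on the Jaccard similarity of their memberships,
#' and one exemplar term is kept per group. Preferences default to the
#' median off-diagonal similarity; standard responsibility/availability
#' message passing with damping.
#'
#' @param significant Data frame of enriched rows (needs a `term` column),
#'   e.g. a filtered [ora()] result.
#' @param sets The [read_gmt()] collection the terms came from.
#' @param background Optional gene universe to restrict memberships to.
#' @param damping Message damping factor in [0.5, 1).
#' @param max_iter Iteration cap.
#' @param conv_iter Stop after this many iterations with unchanged
#'   exemplars.
#' @return List: `exemplars` (term ids), `assignment` (named: term ->
#'   exemplar), `converged`.
#' @export
ap_reduce <- function(significant, sets, background = NULL, damping = 0.9,
                      max_iter = 1000, conv_iter = 50) {
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  terms <- significant$term
  if (length(terms) == 0) stop("no significant terms to reduce")
  members <- lapply(terms, function(id) {
    g <- sets[[id]]$genes
    if (!is.null(background)) g <- intersect(g, background)
    g
  })
  m <- length(terms)
  if (m == 1)
    return(list(exemplars = terms,
                assignment = stats::setNames(terms, terms), converged = TRUE))
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
    u <- length(union(members[[i]], members[[j]]))
    S[i, j] <- if (u == 0) 0 else
      length(intersect(members[[i]], members[[j]])) / u
  }
  ## median off-diagonal similarity, nudged up so exact ties between
  ## "join a cluster" and "be an exemplar" resolve toward more exemplars
  pref <- stats::median(S[row(S) != col(S)]) + 1e-6
  diag(S) <- pref
  ## deterministic tiny jitter to break symmetric ties (standard practice)
  eps <- 1e-10 * (outer(seq_len(m), seq_len(m), function(i, j) i + m * j) %% 7)
  S <- S + eps
  R <- matrix(0, m, m); A <- matrix(0, m, m)
  ex_prev <- integer(0); stable <- 0L; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    AS <- A + S
    mx1 <- apply(AS, 1, max)
    wh1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(m), wh1)] <- -Inf
    mx2 <- apply(AS2, 1, max)
    Rnew <- S - mx1
    Rnew[cbind(seq_len(m), wh1)] <- S[cbind(seq_len(m), wh1)] - mx2
    R <- damping * R + (1 - damping) * Rnew
    ## a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)));
    ## a(k,k) = sum_{i' != k} max(0, r(i',k))
    Anew <- matrix(0, m, m)
    for (k in seq_len(m)) {
      rp <- pmax(R[, k], 0); rp[k] <- R[k, k]
      tot <- sum(rp)
      Anew[, k] <- pmin(0, tot - rp)
      Anew[k, k] <- tot - rp[k]
    }
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, ex_prev)) stable <- stable + 1L else stable <- 0L
    ex_prev <- ex
    if (stable >= conv_iter && length(ex) > 0) break
  }
  converged <- stable >= conv_iter && length(ex_prev) > 0
  if (length(ex_prev) == 0) ex_prev <- which.max(diag(A + R))
  if (!converged) warning("affinity propagation did not converge; returning current exemplars")
  Sx <- S[, ex_prev, drop = FALSE]
  assign_idx <- ex_prev[max.col(Sx, ties.method = "first")]
  assign_idx[ex_prev] <- ex_prev
  list(exemplars = terms[ex_prev],
       assignment = stats::setNames(terms[assign_idx], terms),
       converged = converged)
}
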