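# Independent oracles and generators used across the suite.

# random rooted binary topology by recursive random bipartition
rtopo <- function(labels) {
  rec <- function(lab) {
    if (length(lab) == 1) return(lab)
    idx <- sample(length(lab))
    k <- sample(length(lab) - 1, 1)
    paste0("(", rec(lab[idx[seq_len(k)]]), ",", rec(lab[idx[-seq_len(k)]]), ")")
  }
  ape::read.tree(text = paste0(rec(labels), ";"))
}

# random character over the tips: 0/1 with optional missing fraction
rchar <- function(tree, p0 = 0.35, pna = 0) {
  n <- ape::Ntip(tree)
  x <- ifelse(runif(n) < p0, 0L, 1L)
  x[runif(n) < pna] <- NA_integer_
  stats::setNames(x, tree$tip.label)
}

# clade membership matrix: leaves x nodes, M[l, v] TRUE iff leaf l is in
# the clade below node v (built by direct path-walking, independent of the
# package's postorder machinery)
clade_membership <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  parent <- integer(nn)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  M <- matrix(FALSE, ntip, nn)
  for (l in seq_len(ntip)) {
    v <- l
    repeat {
      M[l, v] <- TRUE
      if (v == ntip + 1L) break
      v <- parent[v]
    }
  }
  M
}

# Exhaustive single-gain / any-loss enumeration oracle for the Dollo
# minimum. Enumerates the gain placement (fixed at the root when
# root_present) and loss-branch subsets in order of increasing size,
# checking whether the implied leaf states match the observed ones
# (missing states unconstrained). Returns the minimum loss count.
dollo_oracle <- function(tree, chr, root_present = TRUE) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  M <- clade_membership(tree)
  x <- as.integer(chr[tree$tip.label])
  obs <- !is.na(x)
  gains <- if (root_present) root else c(0L, seq_len(nn))  # 0 = never gained
  best <- Inf
  for (g in gains) {
    if (g == 0L) {                       # gene never arises: all absent
      if (!any(obs & x == 1L)) best <- min(best, 0)
      next
    }
    below_g <- M[, g]
    D <- setdiff(which(colSums(M & below_g) == colSums(M)), g)  # descendants
    D <- D[colSums(M[, D, drop = FALSE]) < sum(below_g)]
    found <- FALSE
    for (s in 0:length(D)) {
      if (s >= best) break
      combos <- if (s == 0) list(integer(0)) else
        asplit(utils::combn(D, s), 2)
      for (S in combos) {
        cut <- if (length(S) == 0) rep(FALSE, ntip) else
          rowSums(M[, S, drop = FALSE]) > 0
        present <- below_g & !cut
        if (all(present[obs] == (x[obs] == 1L))) {
          best <- min(best, s); found <- TRUE; break
        }
      }
      if (found) break
    }
  }
  best
}

# small helper: strong-signal clade-structured simulation used by several
# recovery tests (each internal branch of the generating tree carries many
# exclusive losses)
strong_signal_sim <- function(seed, n_genes = 300) {
  tree <- ape::read.tree(
    text = "(((A:10,B:10):10,(C:10,D:10):10):10,((E:10,F:10):10,G:30):10);")
  cfg <- dolloloss::loss_sim_config(tree, n_genes = n_genes, base_rate = 0.004,
                                    seed = seed)
  list(tree = tree, sim = dolloloss::simulate_losses(cfg))
}

# Exact hypergeometric upper-tail probabilities, computed once by rational
# arithmetic (sum_{j>=k} C(K,j) C(N-K,n-j) / C(N,n) evaluated with exact
# fractions, then rounded to the nearest double) and frozen here.
exact_hyper_cases <- function() data.frame(
  N = c(20,20,20,200,200,150,200,97,2,10,28,139,105,67,194,166,125,41,74,118,74,152,54,150,50,58,20,69,178,42,150,65,45,119,129,154,118,42,154,135),
  K = c(5,5,5,50,10,75,200,13,1,3,2,48,64,17,80,52,90,34,31,114,4,97,27,39,12,6,18,35,10,23,149,59,3,83,97,137,40,26,14,44),
  n = c(10,10,10,60,10,75,100,41,1,7,1,10,99,53,184,149,21,21,44,46,12,124,44,103,47,57,2,39,176,7,16,51,23,63,66,132,71,1,77,48),
  k = c(5,0,1,40,10,50,100,2,1,3,0,1,31,1,69,38,6,11,0,35,1,94,3,9,12,2,1,27,1,1,7,4,1,52,39,8,10,0,3,15),
  p = c(0.016253869969040248,
        1.0,
        0.9837461300309598,
        5.5018606911754576e-18,
        4.4541437266507297e-17,
        3.881966508516737e-05,
        1.0,
        0.9946827535286126,
        0.5,
        0.2916666666666667,
        1.0,
        0.9879348620533233,
        1.0,
        1.0,
        1.0,
        0.9999995475677609,
        0.9999994673652766,
        1.0,
        1.0,
        1.0,
        0.5151813013090266,
        1.6526125496899922e-10,
        1.0,
        0.9999999999997653,
        0.4304081632653061,
        1.0,
        0.9947368421052631,
        0.0004761929594090331,
        1.0,
        0.9981322786200835,
        1.0,
        1.0,
        0.8914728682170543,
        0.001182449019193924,
        0.9999988693124361,
        1.0,
        0.9999999976247977,
        1.0,
        0.9953464106958481,
        0.6675812598736726)
)
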