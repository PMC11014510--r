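test_that("reconstruction places forced placements and aggregates once per event", {
  t4 <- read_newick("((A,B),(C,D));")

  m1 <- presence_matrix(matrix(c(1L, 1L, 1L, 0L), 4, 1,
    dimnames = list(c("A", "B", "C", "D"), "g1")))
  r1 <- reconstruct_losses(t4, m1)
  expect_equal(r1$per_gene$g1, "D")
  expect_equal(unname(r1$branch_counts[["D"]]), 1L)

  m2 <- presence_matrix(matrix(c(1L, 0L, 0L, 0L), 4, 1,
    dimnames = list(c("A", "B", "C", "D"), "g1")))
  r2 <- reconstruct_losses(t4, m2)
  expect_setequal(r2$per_gene$g1, c("B", "C|D"))
  expect_equal(unname(r2$branch_counts[["C|D"]]), 1L)  # stem counted once
  expect_equal(r2$total_losses, 2)
  expect_equal(nrow(r2$gene_branch), 2)
})

test_that("total reconstructed losses equal the tree score (conservation)", {
  tree <- atlantogenata_tree()
  sim <- simulate_losses(default_sim_config(seed = 5, n_genes = 3000))
  rec <- reconstruct_losses(tree, sim$matrix)
  expect_equal(rec$total_losses, tree_score(tree, sim$matrix))
  expect_equal(sum(rec$branch_counts), sum(lengths(rec$per_gene)))

  # parsimony never infers more events than the truth, and is exact for
  # genes lost at most once
  inf <- lengths(rec$per_gene)
  tru <- lengths(sim$loss_branches)
  expect_true(all(inf <= tru))
  once <- tru <= 1
  expect_equal(inf[once], tru[once])
  # single-loss genes are recovered on the exact generating branch
  single <- names(which(tru == 1))
  expect_true(all(vapply(single, function(g)
    identical(rec$per_gene[[g]], sim$loss_branches[[g]]), TRUE)))
})

test_that("all-absent genes are tallied on root children and reported separately", {
  t4 <- read_newick("((A,B),(C,D));")
  m <- presence_matrix(matrix(0L, 4, 1, dimnames = list(c("A", "B", "C", "D"), "dead")))
  r <- reconstruct_losses(t4, m)
  expect_equal(r$all_absent_genes, "dead")
  expect_setequal(r$per_gene$dead, c("A|B", "C|D"))
})

test_that("branch regression recovers perfect fits, nulls, and planted outliers", {
  t4 <- read_newick("((A:10,B:20):5,(C:30,D:40):15);")
  m <- presence_matrix(matrix(1L, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                                        c("g1", "g2"))))
  rec <- reconstruct_losses(t4, m)

  lens <- dolloloss:::branch_lengths(t4)
  prop <- rec
  prop$branch_counts <- stats::setNames(as.integer(2 * lens[names(rec$branch_counts)]),
                                        names(rec$branch_counts))
  br <- branch_regression(prop, lengths = lens)
  expect_equal(br$r2, 1)
  expect_length(br$outlier_branches, 0)

  cst <- rec
  cst$branch_counts[] <- 7L
  b0 <- branch_regression(cst, lengths = lens)
  expect_equal(b0$r, 0)
  expect_equal(b0$p_value, 1)

  # 10 branches, counts = lengths except one grossly inflated
  tr10 <- read_newick(paste0("(((A:10,B:20):5,(C:30,D:40):15):10,",
                             "((E:12,F:22):6,(G:25,H:35):9):14);"))
  mm <- presence_matrix(matrix(1L, 8, 1, dimnames = list(LETTERS[1:8], "g")))
  rr <- reconstruct_losses(tr10, mm)
  ll <- dolloloss:::branch_lengths(tr10)
  rr$branch_counts <- stats::setNames(as.integer(round(ll[names(rr$branch_counts)])),
                                      names(rr$branch_counts))
  rr$branch_counts[["A"]] <- rr$branch_counts[["A"]] + 200L
  bo <- branch_regression(rr, lengths = ll)
  expect_equal(bo$outlier_branches, "A")

  expect_error(branch_regression(rr, lengths = ll[1]), "no length")
})

test_that("regression p matches a permutation p on a random instance", {
  set.seed(66)
  tree <- atlantogenata_tree()
  sim <- simulate_losses(loss_sim_config(tree, n_genes = 2000,
                                         base_rate = 0.001, seed = 9))
  rec <- reconstruct_losses(tree, sim$matrix)
  br <- branch_regression(rec)
  x <- br$table$length; y <- br$table$count
  robs <- abs(stats::cor(x, y))
  perm <- replicate(10000, abs(stats::cor(x, sample(y))))
  p_perm <- mean(perm >= robs - 1e-12)
  expect_lt(abs(br$p_value - p_perm), 0.02)
})

test_that("the enrichment foreground honours the internal-branch rule", {
  t4 <- read_newick("((A,B),(C,D));")
  st <- cbind(gInt1 = c(1, 1, 0, 0), gInt2 = c(0, 0, 1, 1), gInt3 = c(1, 0, 0, 0),
              gTerm1 = c(1, 1, 1, 0), gTerm2 = c(0, 1, 1, 1), gNone = c(1, 1, 1, 1))
  rownames(st) <- c("A", "B", "C", "D")
  rec <- reconstruct_losses(t4, presence_matrix(st))
  fg <- foreground_from_reconstruction(rec, internal_only = TRUE)
  expect_setequal(fg, c("gInt1", "gInt2", "gInt3"))
  fg_all <- foreground_from_reconstruction(rec, internal_only = FALSE)
  expect_setequal(fg_all, c("gInt1", "gInt2", "gInt3", "gTerm1", "gTerm2"))
})
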