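test_that("newick IO preserves topology, polytomies, labels, lengths", {
  t1 <- read_newick("((A,B),(C,D));")
  expect_equal(ape::Ntip(t1), 4)
  expect_equal(t1$Nnode, 3)

  t2 <- read_newick("((A,B),(C,D),E);")
  expect_equal(length(dolloloss:::phylo_children(t2)[[dolloloss:::phylo_root(t2)]]), 3)

  fx <- atlantogenata_tree()
  expect_equal(ape::Ntip(fx), 17)
  rt <- read_newick(write_newick(fx))
  expect_equal(canonical_topology(rt), canonical_topology(fx))
  expect_equal(sort(dolloloss:::branch_lengths(rt)),
               sort(dolloloss:::branch_lengths(fx)))
  # Paenungulata polytomy survives the round trip
  paen <- stem_branch(rt, c("african_elephant", "asian_elephant",
                            "rock_hyrax", "west_indian_manatee"))
  expect_match(paen, "rock_hyrax")

  expect_error(read_newick("((A,B),(A,C));"), "duplicate")
})

test_that("dollo_fit matches the hand-worked cases", {
  t4 <- read_newick("((A,B),(C,D));")

  f <- dollo_fit(t4, c(A = 1, B = 0, C = 0, D = 0))
  expect_equal(f$losses, 2)
  expect_setequal(f$loss_branches, c("B", "C|D"))
  expect_equal(f$gain_branch, "root")

  expect_equal(dollo_fit(t4, c(A = 1, B = 1, C = 1, D = 1))$losses, 0)

  fq <- dollo_fit(t4, c(A = 1, B = NA, C = 0, D = 0))
  expect_equal(fq$losses, 1)
  expect_equal(fq$loss_branches, "C|D")

  expect_equal(dollo_fit(t4, c(A = 0, B = 0, C = 0, D = 0),
                         root_present = FALSE)$losses, 0)
  # forced-present root: an all-absent gene costs one loss per root child
  expect_equal(dollo_fit(t4, c(A = 0, B = 0, C = 0, D = 0))$losses, 2)

  star <- read_newick("(A,B,C,D);")
  expect_equal(dollo_fit(star, c(A = 1, B = 0, C = 0, D = 0))$losses, 3)

  expect_error(dollo_fit(t4, c(A = 1, Z = 0)), "Z")
})

test_that("dollo_fit equals the placement-enumeration oracle on random instances", {
  set.seed(101)
  for (i in 1:40) {
    tree <- rtopo(LETTERS[1:sample(4:7, 1)])
    chr <- rchar(tree, pna = ifelse(i %% 3 == 0, 0.25, 0))
    for (rp in c(TRUE, FALSE)) {
      expect_equal(dollo_fit(tree, chr, rp)$losses, dollo_oracle(tree, chr, rp),
                   info = paste("rp =", rp, ape::write.tree(tree),
                                paste(chr, collapse = "")))
    }
  }
})

test_that("loss branches are non-nested and consistent with the count", {
  set.seed(7)
  for (i in 1:25) {
    tree <- rtopo(letters[1:6])
    chr <- rchar(tree, pna = 0.15)
    f <- dollo_fit(tree, chr)
    expect_equal(f$losses, length(f$loss_branches))
    sets <- strsplit(f$loss_branches, "|", fixed = TRUE)
    if (length(sets) > 1) {
      for (a in seq_along(sets)) for (b in seq_along(sets)) if (a != b)
        expect_false(all(sets[[a]] %in% sets[[b]]))
    }
  }
})

test_that("tree_score sums per-character fits, is additive, errors on mismatch", {
  t4 <- read_newick("((A,B),(C,D));")
  allp <- presence_matrix(matrix(1L, 4, 3,
    dimnames = list(c("A", "B", "C", "D"), paste0("g", 1:3))))
  expect_equal(tree_score(t4, allp), 0)

  set.seed(5)
  st <- matrix(sample(0:1, 20, TRUE), 4, 5,
               dimnames = list(c("A", "B", "C", "D"), paste0("g", 1:5)))
  m <- presence_matrix(st)
  per <- vapply(1:5, function(j)
    dollo_oracle(t4, stats::setNames(st[, j], rownames(st))), 0)
  expect_equal(tree_score(t4, m), sum(per))
  expect_equal(score_profile(t4, m)$per_gene, stats::setNames(as.integer(per), m$genes))

  dbl <- presence_matrix(cbind(st, st2 = st)[, , drop = FALSE],
                         genes = paste0("h", 1:10))
  expect_equal(tree_score(t4, dbl), 2 * tree_score(t4, m))

  bad <- presence_matrix(matrix(1L, 3, 2,
    dimnames = list(c("A", "B", "X"), c("g1", "g2"))))
  expect_error(tree_score(t4, bad), "X")
})

test_that("collapse_branch forms polytomies and scoring is monotone under collapse", {
  t4 <- read_newick("((A,B),(C,D));")
  c1 <- collapse_branch(t4, "A|B")
  expect_equal(canonical_topology(c1), canonical_topology(read_newick("(A,B,(C,D));")))
  star <- collapse_branch(c1, "C|D")
  expect_equal(star$Nnode, 1)
  expect_equal(dollo_fit(star, c(A = 1, B = 0, C = 0, D = 0))$losses, 3)
  expect_error(collapse_branch(t4, "A"), "leaf")

  # collapsing never decreases, resolving never increases a Dollo score
  set.seed(31)
  for (i in 1:20) {
    tree <- rtopo(LETTERS[1:6])
    ids <- branch_ids(tree)
    internal <- ids[as.integer(names(ids)) > ape::Ntip(tree)]
    b <- sample(internal, 1)
    coll <- collapse_branch(tree, b)
    chr <- rchar(tree)
    expect_gte(dollo_fit(coll, chr)$losses, dollo_fit(tree, chr)$losses)
  }
})

test_that("subtree restriction bounds the full score for subset-present characters", {
  # basis of the branch-and-bound pruning: valid whenever the character has
  # at least one present leaf in the retained subset
  set.seed(13)
  for (i in 1:20) {
    tree <- rtopo(LETTERS[1:7])
    chr <- rchar(tree)
    drop <- sample(tree$tip.label, 2)
    sub <- ape::drop.tip(tree, drop)
    schr <- chr[sub$tip.label]
    if (!any(schr == 1L, na.rm = TRUE)) next
    expect_lte(dollo_fit(sub, schr)$losses, dollo_fit(tree, chr)$losses)
  }
})
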