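test_that("degenerate rates behave exactly as the survival model predicts", {
  tree <- read_newick("((A:10,B:10):5,(C:10,D:10):5);")

  sim0 <- simulate_losses(loss_sim_config(tree, n_genes = 500, base_rate = 0,
                                          seed = 1))
  expect_true(all(sim0$matrix$states == 1L))
  expect_equal(sum(sim0$branch_counts), 0)

  # multiplier 0 suppresses a branch entirely
  simz <- simulate_losses(loss_sim_config(tree, n_genes = 2000, base_rate = 0.02,
    branch_multipliers = c("A|B" = 0), seed = 2))
  expect_equal(unname(simz$branch_counts[["A|B"]]), 0L)
  expect_false(any(vapply(simz$loss_branches, function(b) "A|B" %in% b, TRUE)))

  expect_error(loss_sim_config(read_newick("((A,B),(C,D));"), 10, 0.1),
               "branch lengths")
  expect_error(loss_sim_config(tree, 10, -1), "base_rate")
  expect_error(loss_sim_config(tree, 10, 0.1,
                               branch_multipliers = c(nope = 2)), "unknown")
})

test_that("single-edge loss fraction matches the closed-form survival probability", {
  # two-leaf tree; edge to A has lambda*t = ln 2 => P(loss) = 0.5
  lam <- 0.002
  t_half <- log(2) / lam
  tree <- read_newick(sprintf("(A:%f,B:0.0001);", t_half))
  sim <- simulate_losses(loss_sim_config(tree, n_genes = 10000,
                                         base_rate = lam, seed = 33))
  frac <- mean(sim$matrix$states["A", ] == 0L)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("per-leaf loss fractions follow the product of edge survivals", {
  cfg <- default_sim_config(seed = 44, n_genes = 10000)
  sim <- simulate_losses(cfg)
  tree <- cfg$tree
  lens <- dolloloss:::branch_lengths(tree)
  mult <- stats::setNames(rep(1, length(lens)), names(lens))
  mult[names(cfg$branch_multipliers)] <- cfg$branch_multipliers
  ids <- branch_ids(tree)
  for (leaf in sample(tree$tip.label, 5)) {
    path <- names(lens)[vapply(strsplit(names(lens), "|", fixed = TRUE),
                               function(s) leaf %in% s, TRUE)]
    p_present <- prod(exp(-cfg$base_rate * mult[path] * lens[path]))
    frac <- mean(sim$matrix$states[leaf, ] == 1L)
    se <- sqrt(p_present * (1 - p_present) / cfg$n_genes)
    expect_lt(abs(frac - p_present), 3.5 * se)
  }
})

test_that("losses are irreversible: one gene's loss branches are disjoint clades", {
  sim <- simulate_losses(default_sim_config(seed = 3, n_genes = 3000))
  multi <- sim$loss_branches[lengths(sim$loss_branches) > 1]
  expect_gt(length(multi), 0)  # homoplasy does occur at these rates
  for (br in multi[seq_len(min(200, length(multi)))]) {
    sets <- strsplit(br, "|", fixed = TRUE)
    for (a in seq_along(sets)) for (b in seq_along(sets)) if (a < b)
      expect_length(intersect(sets[[a]], sets[[b]]), 0)
  }
  # and the matrix is consistent with the truth: a gene lost on branch b is
  # absent at exactly the leaves below its loss branches
  lost <- names(sim$loss_branches)[lengths(sim$loss_branches) > 0]
  for (g in sample(lost, 50)) {
    below <- unique(unlist(strsplit(sim$loss_branches[[g]], "|", fixed = TRUE)))
    absent <- sim$matrix$species[sim$matrix$states[, g] == 0L]
    expect_setequal(absent, below)
  }
})

test_that("simulation is byte-identical under a fixed seed and differs across seeds", {
  cfg <- default_sim_config(seed = 9, n_genes = 500)
  s1 <- simulate_losses(cfg)
  s2 <- simulate_losses(cfg)
  expect_identical(s1$matrix$states, s2$matrix$states)
  expect_identical(s1$loss_branches, s2$loss_branches)
  s3 <- simulate_losses(default_sim_config(seed = 10, n_genes = 500))
  expect_false(identical(s1$matrix$states, s3$matrix$states))
})

test_that("fixture files reproduce the truth matrix through the TOGA reader", {
  sim <- simulate_losses(default_sim_config(seed = 21, n_genes = 400))
  d <- withr::local_tempdir()
  write_fixture_files(sim, d)
  files <- list.files(d, pattern = "loss_summ_data")
  expect_length(files, 17)
  per <- lapply(sim$matrix$species, function(sp)
    code_presence(parse_toga_summary(file.path(d, paste0(sp, ".loss_summ_data.tsv")))))
  names(per) <- sim$matrix$species
  m2 <- assemble_matrix(per)
  expect_identical(m2$states[sim$matrix$species, sim$matrix$genes],
                   sim$matrix$states)

  # noise mode: UL relabels flip coding only when UL counts as loss
  d2 <- withr::local_tempdir()
  write_fixture_files(sim, d2, noise_frac = 0.3, seed = 5)
  sp1 <- sim$matrix$species[1]
  recs <- parse_toga_summary(file.path(d2, paste0(sp1, ".loss_summ_data.tsv")))
  expect_true(any(recs$status %in% c("UL", "PI")))
  cons <- code_presence(recs)
  lib <- code_presence(recs, loss_statuses = c("L", "UL"))
  expect_true(sum(lib == 0L) > sum(cons == 0L))
})

test_that("designated enriched sets meet the requested fold enrichment", {
  sim <- simulate_losses(default_sim_config(seed = 13, n_genes = 5000))
  burst <- names(sim$config$branch_multipliers)
  es <- simulate_enriched_sets(sim, n_sets = 30, set_size_range = c(10, 30),
                               n_enriched = 2, focal_branch = burst,
                               boost = 5, seed = 4)
  expect_equal(sum(es$labels$designated), 2)
  expect_length(es$sets, 30)
  genes <- names(sim$loss_branches)
  focal <- genes[vapply(sim$loss_branches, function(b) burst %in% b, TRUE)]
  f0 <- length(focal) / length(genes)
  for (term in es$labels$term[es$labels$designated]) {
    mem <- es$sets[[term]]$genes
    expect_gte(mean(mem %in% focal) / f0, 5 * 0.99)
  }
  # sets are disjoint (a partition of a gene subset)
  all_mem <- unlist(lapply(es$sets, `[[`, "genes"))
  expect_equal(anyDuplicated(all_mem), 0)

  # null fixture: no designated sets
  es0 <- simulate_enriched_sets(sim, n_sets = 10, set_size_range = c(10, 20),
                                n_enriched = 0, focal_branch = burst,
                                boost = 5, seed = 6)
  expect_false(any(es0$labels$designated))
})
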