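test_that("TOGA summary lines parse into typed records", {
  recs <- parse_toga_summary(c("GENE\tMLKL\tL",
                               "TRANSCRIPT\tENST001\tI",
                               "GENE\tRIPK3\tL"))
  expect_equal(nrow(recs), 3)
  expect_equal(recs$entry_class[1], "GENE")
  expect_equal(recs$identifier[1], "MLKL")
  expect_equal(recs$status[1], "L")
  expect_equal(sum(recs$entry_class == "GENE"), 2)

  expect_equal(nrow(parse_toga_summary(character(0))), 0)
  expect_equal(nrow(parse_toga_summary(c("", "  "))), 0)

  # extra columns are tolerated (status vocabulary and layout drift),
  # short lines are not
  expect_equal(parse_toga_summary("GENE\tX\tL\textra")$status, "L")
  expect_error(parse_toga_summary(c("GENE\tA\tL", "GENE\tB")),
               "line 2")
})

test_that("presence coding is total, configurable, and any-loss-wins", {
  recs <- parse_toga_summary(c("GENE\tRIPK3\tL", "GENE\tTP53\tI",
                               "GENE\tX\tUL", "TRANSCRIPT\tY\tL"))
  v <- code_presence(recs)
  expect_equal(v[["RIPK3"]], 0L)
  expect_equal(v[["TP53"]], 1L)
  expect_equal(v[["X"]], 1L)       # UL not a loss under conservative coding
  expect_false("Y" %in% names(v))  # non-GENE rows ignored

  v2 <- code_presence(recs, loss_statuses = c("L", "UL"))
  expect_equal(v2[["X"]], 0L)

  # duplicate rows with conflicting statuses: any loss => 0, with warning
  dup <- parse_toga_summary(c("GENE\tA\tI", "GENE\tA\tL", "GENE\tB\tI"))
  expect_warning(vd <- code_presence(dup), "A")
  expect_equal(vd[["A"]], 0L)
  expect_equal(vd[["B"]], 1L)

  # totality: every GENE record maps to exactly one of {0,1}
  set.seed(4)
  rnd <- data.frame(entry_class = "GENE",
                    identifier = paste0("g", 1:50),
                    status = sample(c("L", "I", "PI", "UL", "M", "PG"), 50, TRUE))
  vr <- code_presence(rnd)
  expect_length(vr, 50)
  expect_true(all(vr %in% 0:1))
})

test_that("matrix assembly respects the universe policy and fill state", {
  per <- list(sp1 = c(A = 1L, B = 0L, C = 1L),
              sp2 = c(A = 1L, B = 1L))
  m <- assemble_matrix(per, "union")
  expect_equal(m$genes, c("A", "B", "C"))
  expect_equal(unname(m$states["sp2", "C"]), 1L)  # fill state
  expect_equal(attr(m, "filled")[["sp2"]], 1L)

  m0 <- assemble_matrix(per, "union", fill_state = 0L)
  expect_equal(unname(m0$states["sp2", "C"]), 0L)

  mi <- assemble_matrix(per, "intersection")
  expect_equal(sort(mi$genes), c("A", "B"))

  mr <- assemble_matrix(per, "reference", reference = c("A", "Z"))
  expect_equal(mr$genes, c("A", "Z"))

  expect_error(assemble_matrix(per["sp1"]), "two species")
  expect_error(assemble_matrix(list(a = c(X = 1L), b = c(Y = 1L)),
                               "intersection"), "empty gene universe")
})

test_that("blacklist filtering matches globs, is idempotent, warns on wipeout", {
  m <- presence_matrix(matrix(1L, 2, 3, dimnames = list(c("s1", "s2"),
                                                        c("KRT5", "MLKL", "KRTAP1"))))
  expect_identical(filter_blacklist(m, character(0))$genes, m$genes)

  f <- filter_blacklist(m, "KRT*")
  expect_equal(f$genes, "MLKL")
  expect_equal(sort(attr(f, "removed")), c("KRT5", "KRTAP1"))
  expect_equal(filter_blacklist(f, "KRT*")$genes, "MLKL")  # idempotent

  expect_warning(w <- filter_blacklist(m, c("KRT*", "MLKL")), "all genes")
  expect_length(w$genes, 0)

  # default blacklist hits the documented families
  expect_true(any(vapply(default_blacklist(), function(p)
    grepl(utils::glob2rx(p), "DEFB103A"), TRUE)))
})

test_that("matrix text formats round-trip and phylip guards name collisions", {
  st <- matrix(c(1L, 0L, NA, 1L, 1L, 0L), 2, 3,
               dimnames = list(c("alpha", "beta"), c("g1", "g2", "g3")))
  m <- presence_matrix(st)

  tsv <- tempfile(fileext = ".tsv")
  write_matrix(m, tsv, "tsv")
  m2 <- read_matrix(tsv, "tsv")
  expect_identical(m2$states, m$states)
  expect_identical(m2$species, m$species)
  expect_identical(m2$genes, m$genes)

  nex <- tempfile(fileext = ".nex")
  write_matrix(m, nex, "nexus")
  m3 <- read_matrix(nex, "nexus")
  expect_identical(m3$states, m$states)
  expect_identical(m3$genes, m$genes)

  phy <- tempfile(fileext = ".phy")
  write_matrix(m, phy, "phylip")
  expect_equal(readLines(phy)[1], "2 3")
  expect_equal(substr(readLines(phy)[2], 1, 10), "alpha     ")

  long <- presence_matrix(matrix(1L, 2, 2,
    dimnames = list(c("samespecies_one", "samespecies_two"), c("a", "b"))))
  expect_error(write_matrix(long, tempfile(), "phylip"), "collide")
})
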