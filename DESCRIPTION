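Package: dolloloss
Title: Dollo Parsimony Phylogenomics of Gene Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of gene loss
    from binary gene presence/absence matrices. Parses TOGA loss-summary
    files into a species-by-gene presence matrix, explores its structure
    with fuzzy c-means and metric multidimensional scaling, infers
    most-parsimonious trees under the Dollo criterion (exact
    branch-and-bound and heuristic search) with bootstrap consensus
    support, tests branch support with a parsimony variant of the
    Shimodaira-Hasegawa test (Templeton and RELL p-values), reconstructs
    ancestral losses on a fixed species tree with per-branch tallies and a
    branch-length regression with outlier flagging, and performs
    hypergeometric over-representation analysis of lost genes with
    Benjamini-Hochberg control and affinity-propagation redundancy
    reduction. Includes a seeded simulator of irreversible gene loss along
    a dated tree (branch-specific rates, loss bursts, enriched gene
    categories) with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
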