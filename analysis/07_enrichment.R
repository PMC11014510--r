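#!/usr/bin/env Rscript

# Step 7 — over-representation analysis of the lost-gene foreground.
#
# Hypergeometric ORA of the internal-branch foreground against simulated
# gene-set fixtures with known designated (enriched) sets, BH FDR control
# at q <= 0.10, and affinity-propagation redundancy reduction of the
# significant terms. With real data the collections would be Reactome
# pathways and subcellular localizations in GMT format.

suppressMessages(library(dolloloss))

seed <- as.integer(Sys.getenv("DOLLOLOSS_SEED", "42"))
m <- read_matrix("results/presence_matrix.tsv", "tsv")
fg <- readLines("results/foreground_genes.txt")

# rebuild the simulation truth to place designated enriched sets
cfg <- default_sim_config(seed = seed)
sim <- simulate_losses(cfg)
burst <- names(cfg$branch_multipliers)
es <- simulate_enriched_sets(sim, n_sets = 40, set_size_range = c(15, 40),
                             n_enriched = 3, focal_branch = burst,
                             boost = 8, seed = seed + 1)

fg <- intersect(fg, m$genes)
res <- ora(fg, m$genes, es$sets, min_size = 5, max_size = 100)
utils::write.table(res, "results/ora_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

sig <- res[res$q <= 0.10, , drop = FALSE]
des <- es$labels$term[es$labels$designated]
message(sprintf("significant at q <= 0.10: %d sets (%d/%d designated recovered)",
                nrow(sig), sum(des %in% sig$term), length(des)))

if (nrow(sig) > 0) {
  ap <- ap_reduce(sig, es$sets, background = m$genes)
  writeLines(ap$exemplars, "results/ora_exemplars.txt")
  message(sprintf("affinity propagation: %d exemplar term(s): %s",
                  length(ap$exemplars), paste(ap$exemplars, collapse = ", ")))
}
message("wrote results/ora_results.tsv, ora_exemplars.txt")
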