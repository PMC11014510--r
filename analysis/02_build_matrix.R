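#!/usr/bin/env Rscript

# Step 2 — parse the per-species TOGA files into a binary presence matrix.
#
# Genes with status "L" are coded 0 (lost), everything else collapses to
# likely-present (1) — the conservative coding. Blacklisted gene families
# with unreliable orthology are removed before any analysis.

suppressMessages(library(dolloloss))

indir <- "results/sim"
files <- list.files(indir, pattern = "\\.loss_summ_data\\.tsv$", full.names = TRUE)
stopifnot(length(files) > 0)

per <- lapply(files, function(f) code_presence(parse_toga_summary(f)))
names(per) <- sub("\\.loss_summ_data\\.tsv$", "", basename(files))

m <- assemble_matrix(per, universe_policy = "union")
bl <- read_blacklist(system.file("extdata", "blacklist.txt", package = "dolloloss"))
m <- filter_blacklist(m, bl)

message(sprintf("matrix: %d species x %d genes; %d blacklisted genes removed",
                length(m$species), length(m$genes), length(attr(m, "removed"))))
message(sprintf("lost states: %d (%.1f%% of cells)", sum(m$states == 0L),
                100 * mean(m$states == 0L)))

write_matrix(m, "results/presence_matrix.tsv", "tsv")
write_matrix(m, "results/presence_matrix.nex", "nexus")
message("wrote results/presence_matrix.{tsv,nex}")
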