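#!/usr/bin/env Rscript
# Stage 1 - synthetic cohort generation.
#
# Builds the seeded synthetic NF1 surveillance cohort (16 healthy donors,
# 23 plexiform neurofibroma, 14 MPNST participants with serial plasma
# draws), simulates cfDNA fragments per sample under the two-component
# tumor/normal mixture, and persists everything downstream stages need:
# the genome grid, cohort tables, per-sample binned counts with and
# without 90-150 bp in silico size selection, and a subsample of fragment
# lengths per clinical group for fragmentomics.

suppressPackageStartupMessages(library(plasmafrac))

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_sim_config(seed = seed)
message("simulating fragment-level cohort (seed ", seed, ") ...")
cohort <- simulate_cohort(cfg, level = "fragments")
grid <- cohort$grid

write_grid(grid, file.path(out, "grid.tsv"))
write.table(cohort$meta, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cohort$sld, file.path(out, "sld.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cohort$therapy, file.path(out, "therapy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cohort$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# binned counts, unselected and after in silico size selection
counts_of <- function(fr) bin_counts(fr, grid)$counts
uns <- vapply(cohort$fragments, counts_of, numeric(n_bins(grid)))
sel <- vapply(cohort$fragments, function(fr)
  counts_of(size_select(fr, 90, 150)), numeric(n_bins(grid)))
write.table(data.frame(grid$bins[, 1:3], uns, check.names = FALSE),
            file.path(out, "counts_unselected.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(grid$bins[, 1:3], sel, check.names = FALSE),
            file.path(out, "counts_selected.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# fragment-length subsample per clinical group (for stage 2)
set.seed(stage_seed(seed, "length-subsample"))
len_tab <- do.call(rbind, lapply(split(cohort$meta$sample_id,
                                       cohort$meta$cohort), function(ids) {
  lens <- unlist(lapply(cohort$fragments[ids], `[[`, "length"),
                 use.names = FALSE)
  data.frame(cohort = cohort$meta$cohort[match(ids[1],
                                               cohort$meta$sample_id)],
             length = sample(lens, min(length(lens), 3e5)))
}))
write.table(len_tab, file.path(out, "fragment_lengths_sample.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

k <- table(cohort$meta$participant_id[cohort$meta$cohort == "MPNST"])
message(sprintf(
  "cohort: %d samples from %d participants; MPNST serial draws mean %.2f (max %d)",
  nrow(cohort$meta), length(unique(cohort$meta$participant_id)),
  mean(k), max(k)))
message("stage 1 outputs written under ", out, "/")
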