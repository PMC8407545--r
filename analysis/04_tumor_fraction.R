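#!/usr/bin/env Rscript
# Stage 4 - tumor-fraction inference.
#
# Fits the two-component mixture with hidden-Markov copy-number states to
# every corrected log2-ratio profile from stage 3, with and without in
# silico size selection, and compares the estimates with the generator's
# truth. Selected-mode estimates quantify the tumor fraction of the
# size-selected fragment pool, which exceeds the unselected fraction
# whenever tumor fragments run short - the enrichment the assay exploits.

suppressPackageStartupMessages(library(plasmafrac))

out <- "results"
grid <- read_grid(file.path(out, "grid.tsv"))
truth <- read.delim(file.path(out, "truth.tsv"))

fit_mode <- function(tag) {
  lr <- read.delim(file.path(out, paste0("log2_ratios_", tag, ".tsv")),
                   check.names = FALSE)
  samples <- setdiff(names(lr), c("chrom", "start", "end"))
  fits <- lapply(samples, function(s) fit_tumor_fraction(lr[[s]], grid))
  data.frame(sample_id = samples,
             tf = vapply(fits, `[[`, numeric(1), "tf"),
             detected = vapply(fits, `[[`, logical(1), "detected"),
             converged = vapply(fits, `[[`, logical(1), "converged"))
}

tf_sel <- fit_mode("selected")
tf_uns <- fit_mode("unselected")
tab <- merge(merge(tf_sel,
                   setNames(tf_uns[, c("sample_id", "tf", "detected")],
                            c("sample_id", "tf_unselected",
                              "detected_unselected")), by = "sample_id"),
             truth[, c("sample_id", "cohort", "true_tf")], by = "sample_id")
write.table(tab[order(tab$sample_id), ], file.path(out, "tf_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

mp <- tab[tab$cohort == "MPNST", ]
message(sprintf("convergence: %d/%d selected fits converged",
                sum(tab$converged), nrow(tab)))
message(sprintf(
  "MPNST: Spearman rho(tf_hat, true tf) = %.3f selected, %.3f unselected",
  cor(mp$tf, mp$true_tf, method = "spearman"),
  cor(mp$tf_unselected, mp$true_tf, method = "spearman")))
message(sprintf(
  "median tf_hat (selected): MPNST %.3f, PN %.3f, healthy %.3f",
  median(tab$tf[tab$cohort == "MPNST"]),
  median(tab$tf[tab$cohort == "PN"]),
  median(tab$tf[tab$cohort == "HEALTHY"])))
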