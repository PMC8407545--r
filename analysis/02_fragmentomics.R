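#!/usr/bin/env Rscript
# Stage 2 - fragment-size analysis.
#
# Kernel-density estimates of cfDNA fragment length per clinical group,
# two-sample Kolmogorov-Smirnov comparison of MPNST versus PN lengths, and
# the log2 density ratio that visualizes where MPNST fragments are
# enriched (short, sub-150 bp lengths) - the rationale for the 90-150 bp
# in silico size-selection window.

suppressPackageStartupMessages(library(plasmafrac))

out <- "results"
len <- read.delim(file.path(out, "fragment_lengths_sample.tsv"))

dens <- lapply(split(len$length, len$cohort), length_density)
ks <- ks_two_sample(len$length[len$cohort == "MPNST"],
                    len$length[len$cohort == "PN"])
lr <- log2_density_ratio(dens$MPNST, dens$PN)

write.table(data.frame(length_bp = dens$MPNST$grid,
                       density_mpnst = dens$MPNST$density,
                       density_pn = dens$PN$density,
                       density_healthy = dens$HEALTHY$density,
                       log2_ratio_mpnst_vs_pn = lr),
            file.path(out, "fragment_length_density.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(ks_D = ks$D, ks_p = ks$p_value,
                          n_mpnst = ks$n1, n_pn = ks$n2,
                          short_fraction_mpnst =
                            mean(len$length[len$cohort == "MPNST"] <= 150),
                          short_fraction_pn =
                            mean(len$length[len$cohort == "PN"] <= 150)),
                     file.path(out, "fragmentomics.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf(
  "MPNST vs PN fragment lengths: KS D = %.4f, p = %.3g; MPNST fragments <=150 bp: %.1f%% vs PN %.1f%%",
  ks$D, ks$p_value, 100 * mean(len$length[len$cohort == "MPNST"] <= 150),
  100 * mean(len$length[len$cohort == "PN"] <= 150)))
crossing <- dens$MPNST$grid[which(diff(sign(lr)) < 0)]
message("log2 density ratio positive below ~",
        paste(head(crossing, 1), collapse = ""), " bp: MPNST enriched for short fragments")
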