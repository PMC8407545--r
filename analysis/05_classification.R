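#!/usr/bin/env Rscript
# Stage 5 - MPNST versus PN classification.
#
# Cross-sectional statistics on the tumor-fraction estimates: three-group
# Kruskal-Wallis with Dunn pairwise comparisons, ROC with Youden-index
# cutpoint (size-selected versus unselected tumor fractions), cutpoint
# classification with Fisher exact test, leave-one-out cross-validated
# penalized logistic regression, the multivariate logistic model with age,
# sex and institution, and the serial-max variant (highest tumor fraction
# per participant).

suppressPackageStartupMessages(library(plasmafrac))

out <- "results"
tab <- read.delim(file.path(out, "tf_table.tsv"))
meta <- read_metadata(file.path(out, "metadata.tsv"))
seed <- 1L

ptf_sel <- participant_tf(tab[, c("sample_id", "tf")], meta, "pretreatment")
rep_sel <- classify_report(ptf_sel, seed = stage_seed(seed, "loocv"))

ptf_uns <- participant_tf(
  setNames(tab[, c("sample_id", "tf_unselected")], c("sample_id", "tf")),
  meta, "pretreatment")
mp_uns <- ptf_uns[ptf_uns$cohort %in% c("MPNST", "PN"), ]
auc_uns <- roc(mp_uns$tf, mp_uns$cohort == "MPNST")$auc

ptf_max <- participant_tf(tab[, c("sample_id", "tf")], meta, "serial_max")
rep_max <- classify_report(ptf_max, seed = stage_seed(seed, "loocv-max"))

report <- list(
  kruskal = list(H = rep_sel$kruskal$H, p = rep_sel$kruskal$p_value,
                 pairwise = rep_sel$kruskal$pairwise),
  roc = list(auc_selected = rep_sel$roc$auc, auc_unselected = auc_uns,
             youden_cutpoint = rep_sel$roc$cutpoint,
             youden_J = rep_sel$roc$youden_J),
  classification = rep_sel$classification,
  loocv = rep_sel$loocv,
  logistic = rep_sel$logistic,
  serial_max = list(auc = rep_max$roc$auc,
                    cutpoint = rep_max$roc$cutpoint,
                    sensitivity = rep_max$classification$sensitivity$estimate,
                    specificity = rep_max$classification$specificity$estimate))
jsonlite::write_json(report, file.path(out, "classification_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf(
  "pretreatment MPNST vs PN: AUC %.3f size-selected vs %.3f unselected",
  rep_sel$roc$auc, auc_uns))
message(sprintf(
  "Youden cutpoint %.4f: sensitivity %.0f%%, specificity %.0f%% (Fisher p = %.3g)",
  rep_sel$roc$cutpoint,
  100 * rep_sel$classification$sensitivity$estimate,
  100 * rep_sel$classification$specificity$estimate,
  rep_sel$classification$fisher_p))
message(sprintf("LOOCV accuracy %.0f%% (95%% CI %.0f%%-%.0f%%)",
                100 * rep_sel$loocv$accuracy,
                100 * rep_sel$loocv$ci[1], 100 * rep_sel$loocv$ci[2]))
co <- rep_sel$logistic$coefficients
if (rep_sel$logistic$separation) {
  message("multivariate logistic: tumor fraction separates the groups ",
          "perfectly (Wald p-values uninformative; separation flagged)")
} else {
  message(sprintf(
    "multivariate logistic: tf p = %.3g; other covariate p >= %.2f",
    co$p_value[co$term == "tf"],
    min(co$p_value[!co$term %in% c("(Intercept)", "tf")])))
}
message(sprintf("serial-max variant: AUC %.3f, sens %.0f%%, spec %.0f%%",
                rep_max$roc$auc,
                100 * rep_max$classification$sensitivity$estimate,
                100 * rep_max$classification$specificity$estimate))
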