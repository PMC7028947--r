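#!/usr/bin/env Rscript

# Fit the clinical-benefit model on the ICI arm: univariable screen,
# adaptive-LASSO selection, multivariable logistic fit with the p <= 0.10
# stay criterion, bootstrap c-statistic, and the derived point score.
# The reference three-factor point score (intercept +1, visceral -2.5,
# NLR>=5 -2, SNV>=10 +3, threshold -1) is then evaluated on both arms.
#
# Outputs: results/model_fit.json, results/model_scores.csv,
#          results/reference_score_performance.csv

suppressPackageStartupMessages({
  library(icipredict)
  library(jsonlite)
})

seed <- 20190104

clinical <- read_clinical_table("results/cohort_ici/clinical.csv")
variants <- read_variant_table("results/cohort_ici/variants.maf.tsv")
cnv <- read_cnv_table("results/cohort_ici/cnv.tsv")

res <- run_pipeline(variants, cnv, clinical, seed = seed)

fit_record <- list(
  seed = seed,
  screened = res$screen$variable[res$screen$selected],
  alasso_selected = res$selected,
  retained = if (is.null(res$model)) character(0) else res$model$variables,
  coefficients = if (is.null(res$model)) NULL else as.list(res$model$coefficients),
  odds_ratios = if (is.null(res$model)) NULL
                else as.list(exp(res$model$coefficients)),
  c_statistic = if (is.null(res$c_statistic)) NULL else res$c_statistic[
    c("c", "conf_low", "conf_high")],
  point_score = if (is.null(res$point_score)) NULL else list(
    intercept = res$point_score$intercept,
    points = as.list(res$point_score$points),
    threshold = res$point_score$threshold,
    range = res$point_score$range)
)
write_json(fit_record, "results/model_fit.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)
if (!is.null(res$scores))
  write.csv(res$scores, "results/model_scores.csv", row.names = FALSE)
cat("retained variables:", paste(fit_record$retained, collapse = ", "), "\n")
if (!is.null(res$c_statistic))
  cat(sprintf("c-statistic %.3f (95%% CI %.3f-%.3f)\n", res$c_statistic$c,
              res$c_statistic$conf_low, res$c_statistic$conf_high))

# Reference point score on both arms: discrimination should be present in
# the ICI arm and absent in the chemotherapy comparator.
psm <- reference_point_score()
perf <- do.call(rbind, lapply(c("ici", "taxane"), function(arm) {
  ft <- read.csv(file.path("results", paste0("features_", arm, ".csv")))
  flags <- ft[c("visceral_mets", "nlr_ge5", "snv_ge10")]
  keep <- complete.cases(flags) & !is.na(ft$cb)
  sc <- score_patient(psm, flags[keep, ])
  m <- classification_metrics(sc$predicted, ft$cb[keep])
  auc <- c_statistic(sc$score, ft$cb[keep], n_boot = 0)$c
  data.frame(arm = arm, n = sum(keep), sensitivity = m$sensitivity,
             specificity = m$specificity, auc = auc)
}))
write.csv(perf, "results/reference_score_performance.csv", row.names = FALSE)
print(transform(perf, sensitivity = round(sensitivity, 3),
                specificity = round(specificity, 3), auc = round(auc, 3)))
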