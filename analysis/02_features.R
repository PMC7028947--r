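#!/usr/bin/env Rscript

# Assemble the per-patient feature table for each arm from the raw tables
# written by 01_simulate.R: SNV count after the putative-germline filter,
# CNV count, signature loadings, CDKN2A/B deletions, DDR flags, and the
# dichotomized indicators.
#
# Outputs: results/features_ici.csv, results/features_taxane.csv

suppressPackageStartupMessages(library(icipredict))

for (arm in c("ici", "taxane")) {
  dir <- file.path("results", paste0("cohort_", arm))
  clinical <- read_clinical_table(file.path(dir, "clinical.csv"))
  variants <- read_variant_table(file.path(dir, "variants.maf.tsv"))
  cnv <- read_cnv_table(file.path(dir, "cnv.tsv"))

  ft <- dichotomize(build_feature_table(clinical, variants, cnv))
  out <- file.path("results", paste0("features_", arm, ".csv"))
  write.csv(ft, out, row.names = FALSE)
  cat(arm, "arm:", nrow(ft), "patients;",
      "median SNV count", stats::median(ft$snv_count),
      "| SNV>=10:", sum(ft$snv_ge10),
      "| CNV>0:", sum(ft$cnv_gt0), "\n")
}
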