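#!/usr/bin/env Rscript

# Simulate the two study arms and write their raw data tables.
#
# Outputs (under results/):
#   cohort_ici/      clinical.csv, variants.maf.tsv, cnv.tsv, truth.json
#   cohort_taxane/   same layout, chemotherapy comparator arm

suppressPackageStartupMessages(library(icipredict))

seed <- 20190101
dir.create("results", showWarnings = FALSE)

ici <- simulate_cohort(cohort_config(n_patients = 62, seed = seed))
write_cohort(ici, "results/cohort_ici")

taxane <- simulate_cohort(cohort_config(n_patients = 62, seed = seed + 1,
                                        arm = "taxane"))
write_cohort(taxane, "results/cohort_taxane")

cat("ICI arm:", nrow(ici$clinical), "patients,",
    nrow(ici$variants), "variants,", nrow(ici$cnv), "CNV calls\n")
cat("taxane arm:", nrow(taxane$clinical), "patients\n")
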