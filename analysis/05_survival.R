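#!/usr/bin/env Rscript

# Survival analyses on the ICI arm: univariable Cox screens for PFS and
# OS, the PFS prognostic-index risk groups (cutoffs -0.29 and 1.54), and
# the integer OS point score (visceral 2, NLR>=5 1, ECOG>=1 1; groups
# 0-2 / 3 / 4) with log-rank tests across groups.
#
# Outputs: results/survival_screen.csv, results/survival_groups.csv

suppressPackageStartupMessages(library(icipredict))

ft <- read.csv("results/features_ici.csv")
ft$cb <- factor(ft$cb, levels = c("NCB", "CB"))

vars <- c("visceral_mets", "nlr_ge5", "snv_ge10", "cnv_gt0", "ecog_ge1")
screen <- rbind(
  cbind(endpoint = "pfs", univariable_screen(ft, vars, outcome = "pfs")),
  cbind(endpoint = "os", univariable_screen(ft, vars, outcome = "os"))
)
write.csv(screen, "results/survival_screen.csv", row.names = FALSE)
print(transform(screen, estimate = round(estimate, 2),
                p_value = signif(p_value, 3)))

# PFS prognostic index from the fitted PFS Cox model over the three score
# components, grouped at the published cutoffs.
cc <- complete.cases(ft[c("visceral_mets", "nlr_ge5", "snv_ge10",
                          "ecog_ge1")])
sub <- ft[cc, ]
pfs_fit <- fit_multivariable(
  sub[c("visceral_mets", "nlr_ge5", "snv_ge10")],
  cbind(sub$pfs_months, sub$pfs_event), family = "cox", stay_alpha = 1)
pi_df <- prognostic_index(pfs_fit$coefficients, sub)
lr_pfs <- km_logrank(sub$pfs_months, sub$pfs_event, pi_df$group)

# OS integer point score and its risk groups.
osc <- os_point_score(sub$visceral_mets == 1, sub$nlr_ge5 == 1,
                      sub$ecog_ge1 == 1)
lr_os <- km_logrank(sub$os_months, sub$os_event, osc$group)

groups <- rbind(
  data.frame(endpoint = "pfs", group = levels(pi_df$group),
             n = as.integer(table(pi_df$group)),
             events = as.integer(tapply(sub$pfs_event, pi_df$group, sum)),
             logrank_p = lr_pfs$test$p_value),
  data.frame(endpoint = "os", group = levels(osc$group),
             n = as.integer(table(osc$group)),
             events = as.integer(tapply(sub$os_event, osc$group, sum)),
             logrank_p = lr_os$test$p_value)
)
write.csv(groups, "results/survival_groups.csv", row.names = FALSE)
print(transform(groups, logrank_p = signif(logrank_p, 3)))
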