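#!/usr/bin/env Rscript
# Stage 3: the statistical comparisons.
#
# On the per-flight table from stage 2 (flights are the independent unit):
#   * ln(St) ~ species * flight_class for perpendicular aquatic flights —
#     does descending flight raise the Strouhal number? (type I ANOVA,
#     eta-squared, Tukey HSD within species, outlier screen)
#   * ln(amplitude) ~ species * fluid for parallel-view flights — is wingbeat
#     amplitude greater in water?
#   * within-species Welch t-tests of up- and downstroke velocity between
#     fluids at the Bonferroni-corrected alpha of 0.05/4 = 0.0125.

suppressPackageStartupMessages(library(alcidkin))

kin <- read_results_table("results/kinematics.csv")
dir.create("results/stats", showWarnings = FALSE)

aq <- kin[kin$fluid == "water" & kin$view == "perpendicular" & is.finite(kin$st), ]
an_st <- fit_lm_sequential_anova(aq, "st", c("species", "flight_class"))
screen <- outlier_test(an_st)
if (screen$result$significant) {
  cat(sprintf("outlier screen: excluded observation %d (Bonferroni p = %.3g)\n",
              screen$result$observation, screen$result$p_value))
} else {
  cat("outlier screen: no significant outlier\n")
}
print(an_st)
tk <- tukey_hsd(an_st, within = "species")
print(as.data.frame(tk), digits = 3)
write.csv(an_st$table, "results/stats/anova_st.csv", row.names = FALSE)
write.csv(tk, "results/stats/posthoc_st.csv", row.names = FALSE)

par_ <- kin[kin$view == "parallel" & is.finite(kin$amplitude_deg), ]
an_amp <- fit_lm_sequential_anova(par_, "amplitude_deg", c("species", "fluid"))
print(an_amp)
write.csv(an_amp$table, "results/stats/anova_amplitude.csv", row.names = FALSE)

alpha_adj <- bonferroni_alpha(0.05, length(unique(par_$species)))
cat(sprintf("Welch tests at Bonferroni-corrected alpha = %.4f\n", alpha_adj))
tt <- list()
for (sp in sort(unique(par_$species))) {
  for (side in c("stroke_vel_up", "stroke_vel_down")) {
    r <- welch_t_test(par_[[side]][par_$species == sp & par_$fluid == "air"],
                      par_[[side]][par_$species == sp & par_$fluid == "water"],
                      paste(sp, "air"), paste(sp, "water"))
    r$response <- side
    r$significant <- r$p_value < alpha_adj
    tt[[paste(sp, side)]] <- r
  }
}
tt <- dplyr::bind_rows(tt)
print(as.data.frame(tt[, c("comparison", "response", "statistic", "df",
                           "p_value", "significant")]), digits = 3)
write.csv(tt, "results/stats/ttests.csv", row.names = FALSE)
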