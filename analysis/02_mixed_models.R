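#!/usr/bin/env Rscript
# Stage 2: group-level models on the simulated trial table.
# Demographics by sex, anthropometric correlates of baseline JVA, and the
# linear mixed models (response ~ sex * level + (1 | participant), REML,
# Satterthwaite tests) for CSA and JVA in each condition, with Tukey-adjusted
# per-level sex contrasts and the baseline-CSA covariate variant.
# Reads results/trials.csv + results/cohort.csv from stage 1.

suppressMessages(library(chitrack))

trials <- read_trials("results/trials.csv")
cohort <- read_cohort("results/cohort.csv")
cohort <- cohort[cohort$id %in% trials$participant, ]

demo <- demographics_tests(cohort)
cat("== Demographics (analysed cohort) ==\n")
print(format(demo, digits = 3), row.names = FALSE)

base <- trials[trials$condition == "HDT" & trials$level == 0, ]
anthro <- anthropometric_correlations(base, cohort)
cat("\n== Baseline JVA vs neck anthropometry (pooled Pearson) ==\n")
print(format(anthro, digits = 3), row.names = FALSE)

summaries <- list(demographics = demo, anthropometry = anthro)
for (cn in c("HDT", "LBNP")) {
  d <- trials[trials$condition == cn, ]
  for (resp in c("csa", "jva")) {
    m <- fit_lmm(d, resp)
    m_adj <- fit_lmm(d, resp, covariate_baseline_csa = TRUE)
    cat(sprintf("\n== %s during %s ==\n", toupper(resp), cn))
    cat(sprintf("level p = %.3g, sex p = %.3g, sex x level p = %.3g\n",
                m$p_values["level"], m$p_values["sex"], m$p_values["interaction"]))
    cat(sprintf("with baseline-CSA covariate: sex p = %.3g, interaction p = %.3g\n",
                m_adj$p_values["sex"], m_adj$p_values["interaction"]))
    sc <- m$sex_contrasts
    cat("per-level sex contrasts (F - M, Tukey-adjusted):\n")
    print(format(sc[order(abs(sc$level)), c("level", "estimate", "SE", "p.value")],
                 digits = 3), row.names = FALSE)
    summaries[[paste(cn, resp, sep = "_")]] <- list(
      p_values = as.list(m$p_values),
      p_values_baseline_adjusted = as.list(m_adj$p_values),
      emmeans = m$emmeans,
      sex_contrasts = sc[, c("level", "estimate", "SE", "t.ratio", "p.value")])
  }
}

jsonlite::write_json(summaries, "results/mixed_models.json",
                     auto_unbox = TRUE, digits = 6, dataframe = "rows")
cat("\nwrote results/mixed_models.json\n")

# Condition-response boxplots by sex and level (the group-level figures)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  trials$level_f <- factor(trials$level, levels = c(0, -3, -6, -20, -30, -40))
  long <- rbind(
    transform(trials, response = "CSA (cm2)", value = csa),
    transform(trials, response = "JVA (a.u.)", value = jva)
  )
  for (cn in c("HDT", "LBNP")) {
    gp <- ggplot(long[long$condition == cn, ],
                 aes(x = level_f, y = value, fill = sex)) +
      geom_boxplot(outlier.size = 0.6) +
      facet_wrap(~response, scales = "free_y") +
      scale_fill_manual(values = c(F = "grey70", M = "white")) +
      labs(x = ifelse(cn == "HDT", "Head-down tilt (deg)", "LBNP (mmHg)"),
           y = NULL, title = paste("Response to", cn, "by sex")) +
      theme_bw()
    ggsave(sprintf("results/fig_%s_boxplots.pdf", tolower(cn)), gp,
           width = 7, height = 3.5)
  }
  cat("wrote results/fig_hdt_boxplots.pdf, results/fig_lbnp_boxplots.pdf\n")
}
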