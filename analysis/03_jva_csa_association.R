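#!/usr/bin/env Rscript
# Stage 3: how well does camera-based JVA track ultrasound CSA?
# Repeated-measures correlations (common slope per sex and condition),
# per-participant regressions with median/IQR summaries, the rank-sum
# comparison of male vs female slopes, and the reliability stratification of
# individual correlations by CSA change (threshold 0.15 cm2).
# Reads results/trials.csv from stage 1.

suppressMessages(library(chitrack))

trials <- read_trials("results/trials.csv")
out <- list()
all_fits <- list()

for (cn in c("HDT", "LBNP")) {
  d <- trials[trials$condition == cn, ]
  cat(sprintf("== %s ==\n", cn))
  for (sx in c("M", "F")) {
    r <- tryCatch(suppressWarnings(rmcorr(d[d$sex == sx, ])),
                  error = function(e) NULL)
    if (!is.null(r)) {
      cat(sprintf("  %s: r_rm = %.2f (95%% CI %.2f, %.2f), p = %.3g, common slope = %.3f a.u./cm2\n",
                  ifelse(sx == "M", "men  ", "women"), r$r_rm, r$ci_low,
                  r$ci_high, r$p, r$common_slope))
      out[[paste(cn, sx, "rmcorr", sep = "_")]] <- r[c("r_rm", "ci_low", "ci_high",
                                                       "p", "common_slope", "df")]
    }
  }
  fits <- individual_fits(d)
  fits$condition <- cn
  all_fits[[cn]] <- fits
  fs <- summarise_fits(fits)
  cat("  individual regressions:\n")
  for (i in seq_len(nrow(fs))) {
    cat(sprintf("    %s: r_median (IQR) = %.2f (%.2f, %.2f); slope median (IQR) = %.2f (%.2f, %.2f)\n",
                ifelse(fs$sex[i] == "M", "men  ", "women"), fs$r_median[i],
                fs$r_q25[i], fs$r_q75[i], fs$slope_median[i], fs$slope_q25[i],
                fs$slope_q75[i]))
  }
  st <- compare_slopes(fits$slope[fits$sex == "M"], fits$slope[fits$sex == "F"])
  cat(sprintf("  male vs female slopes: W = %g, p = %.3g (%s)\n",
              st$statistic, st$p, st$method))
  out[[paste(cn, "fit_summary", sep = "_")]] <- fs
  out[[paste(cn, "slope_test", sep = "_")]] <- st[c("statistic", "p", "method")]
}

pooled <- do.call(rbind, all_fits)
rel <- stratify_reliability(pooled, 0.15)
cat("\n== Reliability of individual correlations by CSA change ==\n")
print(format(rel, digits = 3), row.names = FALSE)
out$reliability <- rel
out$n_fits <- nrow(pooled)

jsonlite::write_json(out, "results/association.json",
                     auto_unbox = TRUE, digits = 6, dataframe = "rows")
cat("wrote results/association.json\n")

# Scatter of JVA vs CSA with per-participant regression lines
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  gp <- ggplot(trials, aes(csa, jva, colour = participant, shape = sex)) +
    geom_point(size = 1.4) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    facet_grid(sex ~ condition, scales = "free") +
    guides(colour = "none") +
    labs(x = "ultrasound CSA (cm2)", y = "peak JVA (a.u.)",
         title = "JVA vs CSA, per participant") +
    theme_bw()
  ggsave("results/fig_association.pdf", gp, width = 7, height = 5.5)
  cat("wrote results/fig_association.pdf\n")
}
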