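# Statistical battery: individual fits, slope comparison, mixed models,
# reliability stratification, anthropometric correlations, demographics.

test_that("individual fits recover exact lines and drop degenerate participants", {
  d <- data.frame(participant = rep(c("a", "b", "c"), each = 4),
                  sex = rep(c("F", "F", "M"), each = 4),
                  csa = c(1, 2, 3, 4, 2, 2, 2, 2, 1, 3, 5, 7),
                  jva = c(2 * c(1, 2, 3, 4) + 1, 1:4, 0.5 * c(1, 3, 5, 7)))
  fits <- individual_fits(d)
  expect_equal(nrow(fits), 2) # "b" has constant x
  a <- fits[fits$participant == "a", ]
  expect_equal(a$slope, 2, tolerance = 1e-12)
  expect_equal(a$r, 1, tolerance = 1e-12)
  expect_equal(a$delta_csa, 3)
  # fewer than three points -> omitted
  d2 <- d[c(1:2, 5:12), ]
  expect_false("a" %in% individual_fits(d2)$participant)
})

test_that("summaries use linear-interpolation quantiles", {
  fits <- data.frame(participant = letters[1:3], sex = "M",
                     slope = c(0.1, 0.2, 0.3), intercept = 0,
                     r = c(0.5, 0.7, 0.9), delta_csa = 1, n = 4)
  s <- summarise_fits(fits)
  expect_equal(s$slope_median, 0.2)
  expect_equal(s$slope_q25, 0.15)
  expect_equal(s$slope_q75, 0.25)
})

test_that("rank-sum slope comparison matches exact enumeration and symmetry", {
  # full separation of 3 vs 3: two-sided exact p = 2 / choose(6, 3)
  res <- compare_slopes(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  # identical multisets: midrank normal approximation, p = 1
  res2 <- compare_slopes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$p, 1)
  # swapping groups leaves p unchanged
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(compare_slopes(a, b)$p, compare_slopes(b, a)$p, tolerance = 1e-12)
  expect_error(compare_slopes(numeric(0), 1), "empty")
})

test_that("mixed-model fixed effects equal OLS when participants are exchangeable", {
  set.seed(21)
  d <- expand.grid(participant = sprintf("P%d", 1:10), level = c(0, -20, -30, -40))
  d$sex <- ifelse(as.integer(sub("P", "", d$participant)) <= 5, "M", "F")
  d$condition <- "LBNP"
  # no participant-level variance at all
  d$jva <- 0.5 + 0.1 * (d$sex == "M") + 0.002 * d$level + rnorm(nrow(d), 0, 0.01)
  m <- fit_lmm(d, "jva")
  lv <- sort(unique(d$level), decreasing = TRUE)[order(abs(sort(unique(d$level), decreasing = TRUE)))]
  dd <- d
  dd$level_f <- factor(dd$level, levels = lv, labels = paste0("L", 1:4))
  dd$sex <- factor(dd$sex, levels = c("F", "M"))
  ols <- lm(jva ~ sex * level_f, data = dd)
  expect_equal(unname(lme4::fixef(m$model)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("balanced noise-free additive effects are recovered", {
  d <- expand.grid(participant = sprintf("P%d", 1:8), level = c(0, -3, -6))
  d$sex <- ifelse(as.integer(sub("P", "", d$participant)) <= 4, "M", "F")
  d$condition <- "HDT"
  set.seed(5)
  d$jva <- 0.4 + 0.12 * (d$sex == "M") + 0.01 * abs(d$level) + rnorm(nrow(d), 0, 1e-4)
  m <- fit_lmm(d, "jva")
  fe <- lme4::fixef(m$model)
  expect_equal(unname(fe["sexM"]), 0.12, tolerance = 0.01)
  expect_equal(unname(fe["level_fL2"]), 0.03, tolerance = 0.01)
  expect_equal(unname(fe["level_fL3"]), 0.06, tolerance = 0.01)
  # balanced-design EMMs equal the cell means
  cells <- aggregate(jva ~ sex + level_f,
                     data = transform(d, level_f = factor(level, levels = c(0, -3, -6),
                                                          labels = c("L1", "L2", "L3"))),
                     FUN = mean)
  emm <- m$emmeans
  merged <- merge(emm, cells, by = c("sex", "level_f"))
  expect_equal(merged$emmean, merged$jva, tolerance = 1e-4)
})

test_that("a sex-mirrored response yields a null sex effect with p near 1", {
  d <- expand.grid(participant = sprintf("P%d", 1:10), level = c(0, -20, -30, -40))
  idx <- as.integer(sub("P", "", d$participant))
  d$sex <- ifelse(idx <= 5, "M", "F")
  d$condition <- "LBNP"
  set.seed(9)
  pat <- rnorm(5, 0, 0.05)[((idx - 1) %% 5) + 1] # same intercepts in both sexes
  # mirrored residuals: each woman duplicates a man's data exactly,
  # so the sex effect is identically zero while residual variance is healthy
  eps <- rnorm(5 * 4, 0, 0.01)
  d$jva <- 0.5 + pat + 0.002 * d$level + eps[((idx - 1) %% 5) + 1 + 5 * (match(d$level, c(0, -20, -30, -40)) - 1)]
  m <- fit_lmm(d, "jva")
  expect_gt(m$p_values["sex"], 0.9)
})

test_that("per-level sex contrasts are extracted with Tukey adjustment", {
  set.seed(33)
  coh <- make_cohort(6, 6, 33)
  tr <- simulate_trial_table(coh, 33)
  m <- fit_lmm(tr[tr$condition == "LBNP", ], "jva")
  expect_equal(nrow(m$sex_contrasts), 4)
  expect_setequal(m$sex_contrasts$level, c(0, -20, -30, -40))
  expect_true(all(m$sex_contrasts$p.value >= 0 & m$sex_contrasts$p.value <= 1))
  # adjusted p never smaller than the unadjusted t probability
  raw <- 2 * pt(-abs(m$sex_contrasts$t.ratio), m$sex_contrasts$df)
  expect_true(all(m$sex_contrasts$p.value >= raw - 1e-12))
  # covariate variant runs and keeps the effect structure
  m2 <- fit_lmm(tr[tr$condition == "LBNP", ], "jva", covariate_baseline_csa = TRUE)
  expect_true("baseline_csa" %in% rownames(m2$anova))
})

test_that("reliability stratification separates small and large CSA changes", {
  fits <- data.frame(participant = sprintf("P%d", 1:10), sex = "M",
                     slope = 0.1, intercept = 0,
                     r = c(-0.5, 0.2, 0.9, 0.95, 0.8, 0.97, 0.98, 0.96, 0.99, 0.97),
                     delta_csa = c(0.05, 0.1, 0.12, 0.2, 0.3, 0.25, 0.4, 0.35, 0.5, 0.45),
                     n = 4)
  s <- stratify_reliability(fits, 0.15)
  expect_equal(s$n, c(3, 7))
  expect_gt(s$iqr_width[s$stratum == "low"], s$iqr_width[s$stratum == "high"])
  # empty low stratum is flagged, not fatal
  s2 <- stratify_reliability(fits, 0)
  expect_true(s2$flag[s2$stratum == "low"])
  expect_equal(s2$n[s2$stratum == "high"], 10)
})

test_that("anthropometric correlations hit the exact endpoint and need variance", {
  coh <- make_cohort(5, 5, 44)
  base <- data.frame(participant = coh$id, jva = coh$scm_thickness)
  res <- anthropometric_correlations(base, coh)
  expect_equal(res$r[res$variable == "scm_thickness"], 1, tolerance = 1e-12)
  expect_error(anthropometric_correlations(base[1:2, ], coh), ">= 3")
})

test_that("demographics tests reduce to the pooled-variance t formula", {
  coh <- make_cohort(6, 5, 55)
  res <- demographics_tests(coh, vars = "scm_thickness")
  f <- coh$scm_thickness[coh$sex == "F"]; m <- coh$scm_thickness[coh$sex == "M"]
  sp <- sqrt(((length(f) - 1) * var(f) + (length(m) - 1) * var(m)) /
               (length(f) + length(m) - 2))
  tstat <- (mean(f) - mean(m)) / (sp * sqrt(1 / length(f) + 1 / length(m)))
  p_hand <- 2 * pt(-abs(tstat), length(f) + length(m) - 2)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
})

test_that("directional summary reports signed sex effects and interaction p-values", {
  coh <- make_cohort(8, 8, 66)
  tr <- simulate_trial_table(coh, 66)
  ds <- directional_summary(tr)
  expect_true(is.finite(ds$jva_hdt_men_minus_women))
  expect_true(ds$jva_lbnp_interaction_p >= 0 && ds$jva_lbnp_interaction_p <= 1)
  # the EMM difference computed from fixed effects equals emmeans' own
  m <- fit_lmm(tr[tr$condition == "LBNP", ], "jva")
  emm <- m$emmeans
  diff_emm <- mean(emm$emmean[emm$sex == "M"]) - mean(emm$emmean[emm$sex == "F"])
  expect_equal(ds$jva_lbnp_men_minus_women, diff_emm, tolerance = 1e-8)
})
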