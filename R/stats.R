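# Statistical battery over trial tables: per-participant regressions,
# rank-sum slope comparison, linear mixed models with sex x level, estimated
# marginal mean contrasts, reliability stratification and anthropometric
# correlations.

#' Per-participant JVA-vs-CSA regressions
#'
#' Ordinary least squares of `y` on `x` within each participant of the given
#' records (filter to one condition before calling). Participants with fewer
#' than `min_points` points or a constant covariate are omitted (their
#' correlation is undefined).
#'
#' @param records data.frame of trial records (one condition).
#' @param x,y,participant Column names.
#' @param min_points Minimum points per participant (default 3).
#' @return data.frame: `participant`, `sex` (if present), `slope`,
#'   `intercept`, `r` (Pearson), `delta_csa` (max - min of `x`), `n`.
#' @export
individual_fits <- function(records, x = "csa", y = "jva",
                            participant = "participant", min_points = 3L) {
  ids <- unique(records[[participant]])
  rows <- lapply(ids, function(id) {
    d <- records[records[[participant]] == id, ]
    xv <- d[[x]]; yv <- d[[y]]
    ok <- is.finite(xv) & is.finite(yv)
    xv <- xv[ok]; yv <- yv[ok]
    if (length(xv) < min_points || stats::var(xv) == 0) return(NULL)
    fit <- stats::lm(yv ~ xv)
    data.frame(participant = id,
               sex = if ("sex" %in% names(d)) d$sex[1] else NA_character_,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = stats::cor(xv, yv),
               delta_csa = max(xv) - min(xv),
               n = length(xv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(participant = character(), sex = character(),
                                      slope = numeric(), intercept = numeric(),
                                      r = numeric(), delta_csa = numeric(),
                                      n = integer())
  rownames(out) <- NULL
  out
}

#' Summarise individual fits by sex
#'
#' Median and interquartile range (linear-interpolation quantiles, type 7) of
#' the per-participant slope and Pearson r.
#'
#' @param fits Output of [individual_fits()].
#' @return data.frame with one row per sex.
#' @export
summarise_fits <- function(fits) {
  do.call(rbind, lapply(split(fits, fits$sex), function(d) {
    qs <- stats::quantile(d$slope, c(0.25, 0.5, 0.75), type = 7)
    qr <- stats::quantile(d$r, c(0.25, 0.5, 0.75), type = 7)
    data.frame(sex = d$sex[1], n = nrow(d),
               slope_median = qs[[2]], slope_q25 = qs[[1]], slope_q75 = qs[[3]],
               r_median = qr[[2]], r_q25 = qr[[1]], r_q75 = qr[[3]])
  }))
}

#' Compare two groups of regression slopes (Wilcoxon rank sum)
#'
#' Two-sided rank-sum test: exact enumeration when the combined sample is at
#' most 20 without ties, otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param slopes_a,slopes_b Numeric vectors (each non-empty).
#' @return List: `statistic` (Mann-Whitney W for the first group), `p`,
#'   `method`.
#' @export
compare_slopes <- function(slopes_a, slopes_b) {
  if (length(slopes_a) < 1 || length(slopes_b) < 1) stop("empty slope group")
  n <- length(slopes_a) + length(slopes_b)
  ties <- anyDuplicated(c(slopes_a, slopes_b)) > 0
  exact <- n <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(slopes_a, slopes_b,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Linear mixed model: response ~ sex * level + (1 | participant)
#'
#' Random-intercept model fit by REML (lme4 via lmerTest), with fixed effects
#' for sex, condition level (as an ordered factor of the administered levels)
#' and their interaction, optionally adjusting for baseline CSA. Fixed-effect
#' F tests use Satterthwaite degrees of freedom. Post hoc, estimated marginal
#' means over the sex-by-level cells are compared pairwise with Tukey
#' adjustment, and the same-level sex contrasts are extracted (the figure
#' annotations).
#'
#' @param records data.frame of trial records for one condition with columns
#'   `participant`, `sex`, `level`, the response, and `baseline_csa` if the
#'   covariate is requested.
#' @param response Response column, `"jva"` or `"csa"`.
#' @param covariate_baseline_csa Add baseline CSA as a fixed covariate.
#' @return List of class `chi_lmm`: `model`, `anova` (Satterthwaite type III
#'   table as data.frame), `p_values` (named: level, sex, interaction),
#'   `emmeans` (cell EMMs), `sex_contrasts` (per-level sex difference with
#'   Tukey-adjusted p), `levels` (mapping of level codes).
#' @export
fit_lmm <- function(records, response = "jva", covariate_baseline_csa = FALSE) {
  d <- records
  lvls <- sort(unique(d$level), decreasing = TRUE)  # 0 first, most extreme last
  lvls <- lvls[order(abs(lvls))]
  if (length(lvls) < 2) stop("need >= 2 levels")
  if (length(unique(d$sex)) < 2) stop("both sexes must be present")
  d$level_f <- factor(d$level, levels = lvls, labels = paste0("L", seq_along(lvls)))
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$.y <- d[[response]]
  d <- d[is.finite(d$.y), ]
  form <- if (covariate_baseline_csa) {
    .y ~ sex * level_f + baseline_csa + (1 | participant)
  } else {
    .y ~ sex * level_f + (1 | participant)
  }
  m <- tryCatch(
    lmerTest::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed model could not be fit (singular design?): ",
                             conditionMessage(e))
  )
  av <- as.data.frame(stats::anova(m, type = 3))
  pv <- c(level = av["level_f", "Pr(>F)"],
          sex = av["sex", "Pr(>F)"],
          interaction = av["sex:level_f", "Pr(>F)"])
  emm <- emmeans::emmeans(m, ~ sex * level_f, lmer.df = "satterthwaite")
  prs <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise"),
                               adjust = "tukey"))
  # same-level sex contrasts, e.g. "F L1 - M L1"
  parts <- strsplit(as.character(prs$contrast), " - ")
  same_level <- vapply(parts, function(p) {
    a <- strsplit(trimws(p[1]), " ")[[1]]
    b <- strsplit(trimws(p[2]), " ")[[1]]
    a[2] == b[2] && a[1] != b[1]
  }, logical(1))
  sex_contrasts <- prs[same_level, , drop = FALSE]
  sex_contrasts$level <- vapply(parts[same_level], function(p) {
    code <- strsplit(trimws(p[1]), " ")[[1]][2]
    lvls[match(code, paste0("L", seq_along(lvls)))]
  }, numeric(1))
  structure(list(model = m, anova = av, p_values = pv,
                 emmeans = as.data.frame(emm), sex_contrasts = sex_contrasts,
                 levels = stats::setNames(lvls, paste0("L", seq_along(lvls))),
                 response = response),
            class = "chi_lmm")
}

#' @export
print.chi_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model on %s (sex x level, random intercept)\n",
              x$response))
  cat(sprintf("  level p = %.4g, sex p = %.4g, interaction p = %.4g\n",
              x$p_values["level"], x$p_values["sex"], x$p_values["interaction"]))
  invisible(x)
}

#' Stratify individual-fit reliability by CSA change
#'
#' Pools individual fits (both conditions, both sexes) and splits them at a
#' CSA-change threshold; reports the interquartile range of the individual
#' Pearson r in each stratum. Wide IQR in the small-change stratum means the
#' attenuation-area association is unreliable when the vessel barely moves.
#'
#' @param fits Pooled output of [individual_fits()].
#' @param threshold CSA-change threshold in cm2 (default 0.15).
#' @return data.frame with one row per stratum: `stratum`, `n`, `r_q25`,
#'   `r_q75`, `iqr_width`, `flag` (TRUE when the stratum has < 2 fits).
#' @export
stratify_reliability <- function(fits, threshold = 0.15) {
  strata <- list(low = fits[fits$delta_csa < threshold, ],
                 high = fits[fits$delta_csa >= threshold, ])
  do.call(rbind, lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) < 2) {
      return(data.frame(stratum = nm, n = nrow(d), r_q25 = NA_real_,
                        r_q75 = NA_real_, iqr_width = NA_real_, flag = TRUE))
    }
    q <- stats::quantile(d$r, c(0.25, 0.75), type = 7)
    data.frame(stratum = nm, n = nrow(d), r_q25 = q[[1]], r_q75 = q[[2]],
               iqr_width = q[[2]] - q[[1]], flag = FALSE)
  }))
}

#' Correlate baseline JVA with neck anthropometry
#'
#' Pooled Pearson correlations (with t-distribution p-values) of baseline JVA
#' against sternocleidomastoid thickness and depth to the vessel: the two
#' optical confounds of attenuation-based volume monitoring.
#'
#' @param baseline_records Trial records at the baseline level (one row per
#'   participant) with a `jva` column.
#' @param cohort Cohort table with `scm_thickness` and `ijv_depth`.
#' @return data.frame: `variable`, `r`, `p`, `n`.
#' @export
anthropometric_correlations <- function(baseline_records, cohort) {
  d <- merge(baseline_records, cohort, by.x = "participant", by.y = "id")
  if (nrow(d) < 3) stop("need >= 3 participants")
  one <- function(v) {
    if (stats::var(d$jva) == 0 || stats::var(d[[v]]) == 0) {
      stop("zero variance in ", v, " or jva")
    }
    ct <- stats::cor.test(d$jva, d[[v]])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
  }
  rbind(one("scm_thickness"), one("ijv_depth"))
}

#' Sex comparisons of cohort demographics
#'
#' Student's two-sample t-tests (equal variances) of each demographic and
#' anatomical variable between men and women, reported as mean (sd) per sex
#' with the p-value - the standard participant-characteristics table.
#'
#' @param cohort Cohort table from [make_cohort()].
#' @param vars Columns to compare.
#' @return data.frame with per-sex mean/sd and `p`.
#' @export
demographics_tests <- function(cohort,
                               vars = c("age", "bsa", "bmi", "csa_baseline",
                                        "scm_thickness", "ijv_depth")) {
  do.call(rbind, lapply(vars, function(v) {
    f <- cohort[[v]][cohort$sex == "F"]
    m <- cohort[[v]][cohort$sex == "M"]
    tt <- stats::t.test(f, m, var.equal = TRUE)
    data.frame(variable = v,
               mean_f = mean(f), sd_f = stats::sd(f),
               mean_m = mean(m), sd_m = stats::sd(m),
               p = tt$p.value)
  }))
}

#' Directional summary of the headline sex effects
#'
#' Lightweight per-cohort summary for large simulation loops: fits the
#' sex-by-level mixed models for JVA (both conditions) and CSA (LBNP) and
#' reports the direction of the sex main effect (estimated marginal mean
#' difference, men minus women, averaged over levels, computed from the
#' fixed effects) together with the Satterthwaite interaction p-values.
#'
#' @param trials Trial table covering both conditions and sexes.
#' @return One-row data.frame: `jva_hdt_men_minus_women`,
#'   `jva_lbnp_men_minus_women`, `csa_lbnp_men_minus_women`,
#'   `jva_hdt_interaction_p`, `jva_lbnp_interaction_p`.
#' @export
directional_summary <- function(trials) {
  emm_diff <- function(m) {
    fe <- lme4::fixef(m$model)
    k <- length(m$levels)
    ints <- fe[grep("^sexM:level_f", names(fe))]
    unname(fe["sexM"] + sum(ints) / k)
  }
  jh <- fit_lmm(trials[trials$condition == "HDT", ], "jva")
  jl <- fit_lmm(trials[trials$condition == "LBNP", ], "jva")
  cl <- fit_lmm(trials[trials$condition == "LBNP", ], "csa")
  data.frame(
    jva_hdt_men_minus_women = emm_diff(jh),
    jva_lbnp_men_minus_women = emm_diff(jl),
    csa_lbnp_men_minus_women = emm_diff(cl),
    jva_hdt_interaction_p = unname(jh$p_values["interaction"]),
    jva_lbnp_interaction_p = unname(jl$p_values["interaction"])
  )
}
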