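# Analytic trial-table generator: the closed-form counterpart of the full
# optical pipeline, for statistical simulation at scale. Both instruments
# observe the peak vessel state of the trial; the camera-side JVA follows the
# rendered pipeline's closed form (realized slope x peak CSA + muscle +
# background) and the ultrasound adds operator noise.

#' Simulate a trial table without rendering video
#'
#' For every participant and every condition level, computes the ground-truth
#' mean CSA, forms the peak vessel state (mean CSA times one plus the
#' pulsatile modulation amplitude), and draws the two observations:
#' `csa = peak state + N(0, csa_noise_sd)` (truncated positive) and
#' `jva = slope * peak state + 2 mu_myo scm + background + N(0, jva_noise_sd)`,
#' with `slope` the participant's realized attenuation-vs-CSA slope (or a
#' fixed `common_slope` for parameter-recovery studies). `baseline_csa` is
#' the participant's observed CSA at 0 deg head-down tilt.
#'
#' With `dropout = TRUE`, one woman is removed entirely and one man loses his
#' LBNP block, reproducing the analysed-cohort structure.
#'
#' @param cohort Cohort table from [make_cohort()].
#' @param seed Master integer seed.
#' @param config Configuration list (`table` block holds the noise sds).
#' @param csa_noise_sd,jva_noise_sd Measurement noise, cm2 and a.u.
#' @param common_slope Optional fixed common slope overriding the
#'   participant-specific realized slopes.
#' @param dropout Apply the analysed-cohort exclusions.
#' @return data.frame of trial records: `participant`, `sex`, `condition`,
#'   `level`, `csa`, `jva`, `baseline_csa`.
#' @export
simulate_trial_table <- function(cohort, seed, config = default_config(),
                                 csa_noise_sd = config$table$csa_noise_sd,
                                 jva_noise_sd = config$table$jva_noise_sd,
                                 common_slope = NULL,
                                 dropout = FALSE) {
  cc <- config$cohort
  peak_mod <- config$dynamics$cardiac_amp + config$dynamics$resp_amp
  lv <- condition_levels()
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    slope <- if (is.null(common_slope)) realized_slope(p, config) else common_slope
    set.seed(derive_seed(seed, p$id, "table"))
    out <- lapply(names(lv), function(cn) {
      vapply(lv[[cn]], function(l) {
        ct <- true_csa(p, cn, l, cc$lbnp_frac, cc$csa_floor)
        peak <- ct * (1 + peak_mod)
        csa_obs <- peak + stats::rnorm(1, 0, csa_noise_sd)
        while (csa_obs <= 0) csa_obs <- peak + stats::rnorm(1, 0, csa_noise_sd)
        jva_obs <- slope * peak +
          2 * config$optics$mu_myo * p$scm_thickness +
          config$optics$background_mu + stats::rnorm(1, 0, jva_noise_sd)
        c(csa = csa_obs, jva = jva_obs)
      }, numeric(2))
    })
    data.frame(
      participant = p$id, sex = p$sex,
      condition = rep(names(lv), vapply(lv, length, integer(1))),
      level = unlist(lv, use.names = FALSE),
      csa = unlist(lapply(out, function(m) m["csa", ])),
      jva = unlist(lapply(out, function(m) m["jva", ])),
      stringsAsFactors = FALSE
    )
  })
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  base <- trials[trials$condition == "HDT" & trials$level == 0,
                 c("participant", "csa")]
  names(base)[2] <- "baseline_csa"
  trials <- merge(trials, base, by = "participant", sort = FALSE)
  if (isTRUE(dropout)) trials <- apply_dropout(trials, cohort, seed)
  trials
}

# Remove one woman entirely and one man's LBNP block (seeded choice),
# mirroring the analysed-cohort structure.
apply_dropout <- function(trials, cohort, seed) {
  set.seed(derive_seed(seed, "dropout"))
  f_ids <- cohort$id[cohort$sex == "F"]
  m_ids <- cohort$id[cohort$sex == "M"]
  drop_f <- sample(f_ids, 1)
  drop_m <- sample(m_ids, 1)
  trials <- trials[trials$participant != drop_f, ]
  trials[!(trials$participant == drop_m & trials$condition == "LBNP"), ]
}

#' Write or read a trial table as CSV
#' @param trials Trial records data.frame.
#' @param path File path.
#' @return `read_trials()` returns the data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
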