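# Cohort generation: participant anatomy/physiology, trial schedules and
# ground-truth vessel state at every condition level.

# Truncated normal by inverse-CDF: deterministic given the RNG state and
# vectorized. Truncation at +/- 3 sd and at a positive floor keeps every
# anatomical parameter physical.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

sample_field <- function(mean, sd, floor = 1e-6) {
  rtruncnorm(1, mean, sd, lower = max(mean - 3 * sd, floor), upper = mean + 3 * sd)
}

#' Mean of the sampler's truncated normal for a given field
#'
#' Closed form of the expectation the cohort sampler actually targets
#' (truncation at 3 sd and at the positive floor); used to state sampler
#' convergence exactly.
#'
#' @param mean,sd Nominal mean and sd.
#' @param floor Lower truncation bound.
#' @return Expected value of the truncated normal draw.
#' @export
truncnorm_mean <- function(mean, sd, floor = 1e-6) {
  a <- (max(mean - 3 * sd, floor) - mean) / sd
  b <- 3
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Generate a synthetic participant cohort
#'
#' Samples one parameter set per participant from independent truncated normal
#' distributions (3 sd, positive) around the per-sex reference means of
#' [table1_parameters()]. The male relative hemoglobin mean is 1.15x the
#' female mean. The participant-specific attenuation-vs-CSA slope `jva_gain`
#' (a.u. per cm2) is lognormal around the per-sex median individual slopes
#' (men 0.23, women 0.05 a.u./cm2), with log-sd matched to the printed slope
#' interquartile ranges. `hdt_delta` is the participant's CSA increase at
#' -6 deg head-down tilt (cm2); heart and respiratory rates are uniform over
#' 60-80 bpm and 12-16 breaths/min.
#'
#' Each participant is sampled from their own seed substream, so a cohort of
#' any size contains the same individuals for the same master seed.
#'
#' @param n_men,n_women Positive participant counts.
#' @param seed Master integer seed.
#' @param config Configuration list, see [default_config()].
#' @return A data.frame with one row per participant: `id`, `sex` ("M"/"F"),
#'   `age`, `bsa`, `bmi`, `hb_scale`, `scm_thickness`, `ijv_depth`,
#'   `csa_baseline`, `jva_gain`, `hdt_delta`, `heart_rate`, `resp_rate`.
#' @export
make_cohort <- function(n_men, n_women, seed, config = default_config()) {
  if (n_men < 1 || n_women < 1) stop("n_men and n_women must both be >= 1")
  tab <- table1_parameters()
  cc <- config$cohort
  sexes <- c(rep("M", n_men), rep("F", n_women))
  ids <- c(sprintf("M%02d", seq_len(n_men)), sprintf("F%02d", seq_len(n_women)))
  rows <- lapply(seq_along(ids), function(i) {
    sx <- sexes[i]
    set.seed(derive_seed(seed, ids[i], "params"))
    gmed <- cc$gain_median[[sx]]
    gsd <- cc$gain_log_sd[[sx]]
    data.frame(
      id = ids[i], sex = sx,
      age = sample_field(tab$age[[sx]][1], tab$age[[sx]][2]),
      bsa = sample_field(tab$bsa[[sx]][1], tab$bsa[[sx]][2]),
      bmi = sample_field(tab$bmi[[sx]][1], tab$bmi[[sx]][2]),
      hb_scale = sample_field(tab$hb_scale[[sx]][1], tab$hb_scale[[sx]][2]),
      scm_thickness = sample_field(tab$scm_thickness[[sx]][1], tab$scm_thickness[[sx]][2]),
      ijv_depth = sample_field(tab$ijv_depth[[sx]][1], tab$ijv_depth[[sx]][2]),
      # baseline CSA truncated above the collapse floor: the negative-pressure
      # response curve is undefined for a vessel already below it, and a
      # supine IJV under 0.1 cm2 is not a measurable vessel in this protocol
      csa_baseline = sample_field(tab$csa_baseline[[sx]][1], tab$csa_baseline[[sx]][2],
                                  floor = cc$csa_min),
      jva_gain = exp(rtruncnorm(1, log(gmed), gsd, log(gmed) - 3 * gsd, log(gmed) + 3 * gsd)),
      hdt_delta = rtruncnorm(1, cc$hdt_delta_mean, cc$hdt_delta_sd,
                             lower = max(cc$hdt_delta_mean - 3 * cc$hdt_delta_sd, 0.02),
                             upper = cc$hdt_delta_mean + 3 * cc$hdt_delta_sd),
      heart_rate = stats::runif(1, 60, 80),
      resp_rate = stats::runif(1, 12, 16),
      stringsAsFactors = FALSE
    )
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort
}

#' Write or read a cohort table as CSV
#' @param cohort Cohort data.frame from [make_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Randomized trial schedule for one participant
#'
#' The two condition blocks (HDT, LBNP) are administered in random order per
#' participant; the levels inside each block always follow the fixed printed
#' sequence (0, -3, -6 deg; 0, -20, -30, -40 mmHg).
#'
#' @param participant One cohort row (data.frame or list with `id`).
#' @param seed Master integer seed.
#' @return data.frame with columns `condition`, `level` (7 rows).
#' @export
schedule_trials <- function(participant, seed) {
  lv <- condition_levels()
  set.seed(derive_seed(seed, participant$id, "schedule"))
  order <- sample(names(lv))
  do.call(rbind, lapply(order, function(cn) {
    data.frame(condition = cn, level = lv[[cn]], stringsAsFactors = FALSE)
  }))
}

#' Ground-truth mean CSA at a condition level
#'
#' Deterministic per-participant response curve. Head-down tilt distends the
#' vessel linearly with tilt angle up to the participant's `hdt_delta` at
#' -6 deg. Negative pressure empties it linearly toward a collapse floor:
#' at -40 mmHg the vessel has lost `lbnp_frac` of its distance to the floor,
#' so smaller (typically male) veins approach collapse first. At level 0 both
#' curves equal `csa_baseline`.
#'
#' @param participant One cohort row.
#' @param condition `"HDT"` or `"LBNP"`.
#' @param level Level within the condition (deg or mmHg, see
#'   [condition_levels()]).
#' @param lbnp_frac Fraction of (baseline - floor) removed at -40 mmHg.
#' @param csa_floor Collapse floor in cm2.
#' @return Mean CSA in cm2 (scalar).
#' @export
true_csa <- function(participant, condition, level,
                     lbnp_frac = 0.75, csa_floor = 0.05) {
  lv <- condition_levels()
  if (!condition %in% names(lv)) stop("unknown condition: ", condition)
  if (!level %in% lv[[condition]]) {
    stop("level ", level, " not valid for ", condition)
  }
  base <- participant$csa_baseline
  if (condition == "LBNP" && base <= csa_floor) {
    stop("csa_baseline must exceed the collapse floor for the LBNP response")
  }
  if (condition == "HDT") {
    base + participant$hdt_delta * abs(level) / 6
  } else {
    csa_floor + (base - csa_floor) * (1 - lbnp_frac * abs(level) / 40)
  }
}

#' Instantaneous vessel dynamics for one acquisition
#'
#' Builds the ground-truth CSA time series
#' `CSA(t) = mean_csa * (1 + cardiac(t) + resp(t))`. The cardiac component is
#' the venous pulse: anti-phase with the arterial photoplethysmogram produced
#' by [generate_ppg()] under the same seed and heart rate (venous volume is
#' high when arterial inflow is low). The respiratory component is a sinusoid
#' at the participant's breathing rate with seeded phase. Both modulation
#' amplitudes are fractions of the mean CSA and must stay below 50%.
#'
#' @param participant One cohort row.
#' @param condition,level Condition level, passed to [true_csa()].
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed shared with the reference PPG.
#' @param cardiac_amp,resp_amp Modulation amplitudes (fractions of mean CSA).
#' @param ... Passed to [true_csa()] (`lbnp_frac`, `csa_floor`).
#' @return List: `mean_csa`, `csa_t` (length `duration*fs`), `cardiac`,
#'   `resp`, `signals` (the PPG/R-spike reference, see [generate_ppg()]),
#'   `fs`, `duration`.
#' @export
render_dynamics <- function(participant, condition, level, duration, fs, seed,
                            cardiac_amp = 0.05, resp_amp = 0.03, ...) {
  stopifnot(duration > 0, fs > 0)
  if (cardiac_amp + resp_amp >= 0.5) {
    stop("combined modulation amplitude must stay below 50% of mean CSA")
  }
  mean_csa <- true_csa(participant, condition, level, ...)
  signals <- generate_ppg(participant$heart_rate, duration, fs, seed)
  nT <- length(signals$ppg)
  t <- (seq_len(nT) - 1) / fs
  cardiac <- -cardiac_amp * normalize_unit(signals$ppg)
  set.seed(derive_seed(seed, "resp-phase"))
  phase <- stats::runif(1, 0, 2 * pi)
  resp <- resp_amp * sin(2 * pi * participant$resp_rate / 60 * t + phase)
  list(mean_csa = mean_csa, csa_t = mean_csa * (1 + cardiac + resp),
       cardiac = cardiac, resp = resp, signals = signals,
       fs = fs, duration = duration)
}

# Zero-mean, max-abs-one normalization used to turn the PPG shape into a
# modulation waveform.
normalize_unit <- function(x) {
  x <- x - mean(x)
  m <- max(abs(x))
  if (m == 0) return(x)
  x / m
}
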