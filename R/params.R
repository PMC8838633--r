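#' Reference cohort parameters
#'
#' Per-sex sampling distributions (mean, sd) for the participant generator.
#' Anatomy and baseline hemodynamics are parameterized from a young healthy
#' cohort (9 women / 10 men): internal jugular vein cross-sectional area (CSA)
#' and jugular venous attenuation (JVA) supine at 0 deg tilt, sternocleidomastoid
#' thickness, skin-to-vessel depth, plus demographics. Hemoglobin is expressed
#' as a relative scale (female mean 1.0) with the male mean 15% higher, the
#' accepted adult sex difference.
#'
#' @return Nested list: one element per field, each holding `F` and `M`
#'   numeric vectors `c(mean, sd)`. Units: cm2 (csa), a.u. (jva), cm
#'   (scm_thickness, ijv_depth), years (age), m2 (bsa), kg/m2 (bmi),
#'   dimensionless (hb_scale).
#' @export
table1_parameters <- function() {
  list(
    age           = list(F = c(24, 4),     M = c(25, 5)),
    bsa           = list(F = c(1.61, 0.16), M = c(1.90, 0.15)),
    bmi           = list(F = c(22.2, 2.1), M = c(23.7, 3.1)),
    csa_baseline  = list(F = c(0.60, 0.18), M = c(0.44, 0.25)),
    jva_baseline  = list(F = c(0.51, 0.07), M = c(0.61, 0.09)),
    scm_thickness = list(F = c(0.81, 0.14), M = c(1.13, 0.23)),
    ijv_depth     = list(F = c(1.17, 0.12), M = c(1.51, 0.21)),
    hb_scale      = list(F = c(1.00, 0.08), M = c(1.15, 0.09))
  )
}

#' Default experiment configuration
#'
#' Flat-ish list of every tunable in the pipeline: scene geometry, optical
#' coefficients, vessel dynamics, camera noise, CHI extraction settings,
#' ultrasound simulation, cohort effect sizes and the analytic trial-table
#' noise levels. All values are documented in the methods vignette; everything
#' can be overridden by name.
#'
#' @param ... Named overrides applied on top of the defaults (one level deep:
#'   e.g. `noise = list(enabled = FALSE)` replaces only the named entries of
#'   the `noise` block).
#' @return Named list of configuration blocks.
#' @export
default_config <- function(...) {
  cfg <- list(
    scene = list(
      height = 64L, width = 64L, pitch_cm = 0.05,
      midline_row = 24L,
      vessel_rows = 33:56, vessel_col_center = 32,
      artery_rows = 33:52, artery_cols = 12:13,
      target_rows = 1:8, target_cols = 1:8, r_ref = 0.95
    ),
    optics = list(
      mu_myo = 0.056,        # effective myoglobin absorbance, per cm path
      background_mu = 0.383, # static skin/tissue absorbance, a.u.
      depth_delta_cm = 1.0,  # depth-sensitivity length scale
      hb_ref = 1.075,        # hemoglobin scale at which jva_gain is anchored
      depth_ref_cm = 1.34,   # vessel depth at which jva_gain is anchored
      i0 = 1000,             # illumination intensity, camera counts
      artery_base = 0.05, artery_amp = 0.02
    ),
    dynamics = list(
      cardiac_amp = 0.05,  # fraction of mean CSA
      resp_amp = 0.03,     # fraction of mean CSA
      ppg_jitter_sd = 0.03, ptt_s = 0.2
    ),
    noise = list(enabled = TRUE, shot_scale = 0.01, read_sd = 1.0),
    chi = list(
      r_threshold = -0.3, connectivity = 8L,
      kalman_process_var = 1e-5, kalman_meas_var = 1e-4,
      cardiac_band_hz = c(0.7, 3.0),
      roi_max_extent_cm = 1.0, smooth_window = 0L
    ),
    video = list(duration_s = 30, fs = 60),
    fast_video = list(duration_s = 10, fs = 30),
    ultrasound = list(duration_s = 5, fps = 23, noise_sd = 0.02),
    cohort = list(
      n_men = 10L, n_women = 10L,
      lbnp_frac = 0.75, csa_floor = 0.05, csa_min = 0.10,
      hdt_delta_mean = 0.19, hdt_delta_sd = 0.08,
      gain_median = c(F = 0.05, M = 0.23),
      gain_log_sd = c(F = 0.73, M = 0.85),
      dropout = TRUE
    ),
    table = list(csa_noise_sd = 0.02, jva_noise_sd = 0.003)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Read / write a configuration file
#'
#' Configurations are stored as flat YAML so every effect size, noise amplitude
#' and seed used in a run can be inspected and edited by hand.
#'
#' @param config Configuration list (see [default_config()]).
#' @param path File path.
#' @return `read_config()` returns the configuration list merged over the
#'   defaults; `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Condition levels
#'
#' The two fluid-shift challenges and their ordered within-block levels:
#' head-down tilt at 0, -3, -6 degrees and lower-body negative pressure at
#' 0, -20, -30, -40 mmHg. Levels are always administered in this printed
#' sequence; only the block order is randomized per participant.
#'
#' @return Named list of numeric level vectors.
#' @export
condition_levels <- function() {
  list(HDT = c(0, -3, -6), LBNP = c(0, -20, -30, -40))
}

# Deterministic substream derivation: hash the master seed and a list of
# labels into [1, 2^31 - 2] so any trial is reproducible in isolation.
derive_seed <- function(master, ...) {
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    for (cd in utf8ToInt(p)) h <- (h * 31 + cd) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}
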