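# End-to-end experiment runner: cohort -> rendered trials -> JVA and CSA
# extraction -> statistical battery.

#' Simulate one fully rendered trial
#'
#' Builds the participant's scene, generates the shared cardiac/respiratory
#' dynamics and reference PPG (one heart per participant: the dynamics seed
#' depends on the participant only, so the pulse waveform is identical across
#' levels while noise is drawn per trial), renders the near-infrared stack,
#' runs the CHI extraction chain, and measures CSA from a simulated
#' ultrasound cine loop.
#'
#' @param participant Cohort row.
#' @param condition,level Condition level.
#' @param seed Master integer seed.
#' @param config Configuration list.
#' @param fast Use the reduced acquisition (shorter, lower frame rate) for
#'   desk-scale runs.
#' @return List: `jva` (peak, a.u., `NA` if no venous ROI was found), `csa`
#'   (cm2), `roi`, `iou` (intersection-over-union of the localized ROI with
#'   the ground-truth down-sampled vessel footprint), `mean_csa_true`.
#' @export
simulate_trial <- function(participant, condition, level, seed,
                           config = default_config(), fast = FALSE) {
  vid <- if (fast) config$fast_video else config$video
  cc <- config$cohort
  scene <- build_scene(participant, config)
  dyn_seed <- derive_seed(seed, participant$id, "dynamics")
  dyn <- render_dynamics(participant, condition, level,
                         vid$duration_s, vid$fs, dyn_seed,
                         config$dynamics$cardiac_amp, config$dynamics$resp_amp,
                         lbnp_frac = cc$lbnp_frac, csa_floor = cc$csa_floor)
  stack <- render_stack(scene, participant, dyn, dyn$signals, config$noise,
                        seed = derive_seed(seed, participant$id, condition, level))
  chi <- chi_extract(stack, dyn$signals$ppg, scene, config)
  loop <- make_cineloop(participant, condition, level, dyn_seed,
                        config$ultrasound$duration_s, config$ultrasound$fps,
                        cardiac_amp = config$dynamics$cardiac_amp,
                        resp_amp = config$dynamics$resp_amp,
                        lbnp_frac = cc$lbnp_frac, csa_floor = cc$csa_floor)
  us_noise <- if (isTRUE(config$noise$enabled)) config$ultrasound$noise_sd else 0
  csa_m <- measure_csa(loop, us_noise,
                       derive_seed(seed, participant$id, condition, level, "us"))
  iou <- if (is.null(chi)) NA_real_ else {
    roi_iou(chi$roi$pixels, which(scene$vessel_mask_ds, arr.ind = TRUE))
  }
  list(jva = if (is.null(chi)) NA_real_ else chi$jva$peak,
       csa = csa_m$value, roi = if (is.null(chi)) NULL else chi$roi,
       iou = iou, mean_csa_true = dyn$mean_csa)
}

#' Intersection-over-union of two pixel sets
#' @param a,b Two-column matrices of (row, col) coordinates.
#' @return IoU in `[0, 1]`.
#' @export
roi_iou <- function(a, b) {
  ka <- paste(a[, 1], a[, 2]); kb <- paste(b[, 1], b[, 2])
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Run the full synthetic experiment
#'
#' Generates the cohort, schedules and renders every trial, extracts peak JVA
#' and measured CSA, assembles the trial table (with baseline CSA), applies
#' the analysed-cohort dropouts if configured, and runs the statistical
#' battery. Deterministic given the master seed.
#'
#' @param seed Master integer seed.
#' @param config Configuration list.
#' @param fast Use the reduced acquisition per trial.
#' @param render With `FALSE`, skip video rendering and use the analytic
#'   trial-table generator (same cohort and ground truth; used for large
#'   statistical simulations).
#' @param progress Print one line per participant.
#' @return List: `cohort`, `trials` (trial table), `stats` (see
#'   [run_stats_battery()]).
#' @export
run_experiment <- function(seed, config = default_config(), fast = FALSE,
                           render = TRUE, progress = FALSE) {
  cc <- config$cohort
  cohort <- make_cohort(cc$n_men, cc$n_women, seed, config)
  if (!render) {
    trials <- simulate_trial_table(cohort, seed, config, dropout = cc$dropout)
  } else {
    rows <- list()
    for (i in seq_len(nrow(cohort))) {
      p <- cohort[i, ]
      if (progress) message("participant ", p$id)
      sched <- schedule_trials(p, seed)
      for (j in seq_len(nrow(sched))) {
        tr <- simulate_trial(p, sched$condition[j], sched$level[j], seed,
                             config, fast = fast)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p$id, sex = p$sex,
          condition = sched$condition[j], level = sched$level[j],
          csa = tr$csa, jva = tr$jva, iou = tr$iou,
          stringsAsFactors = FALSE)
      }
    }
    trials <- do.call(rbind, rows)
    base <- trials[trials$condition == "HDT" & trials$level == 0,
                   c("participant", "csa")]
    names(base)[2] <- "baseline_csa"
    trials <- merge(trials, base, by = "participant", sort = FALSE)
    if (isTRUE(cc$dropout)) trials <- apply_dropout(trials, cohort, seed)
    trials <- trials[!is.na(trials$jva), ]  # trials without a venous ROI drop
  }
  stats <- run_stats_battery(trials, cohort)
  list(cohort = cohort, trials = trials, stats = stats)
}

#' Statistical battery over a trial table
#'
#' Per condition: linear mixed models (with and without the baseline-CSA
#' covariate) for both CSA and JVA, repeated-measures correlations per sex,
#' individual regressions with per-sex summaries, and the rank-sum comparison
#' of male vs female slopes. Pooled across conditions: reliability
#' stratification at 0.15 cm2 CSA change and the anthropometric correlations
#' of baseline JVA.
#'
#' @param trials Trial table.
#' @param cohort Cohort table (for anthropometry).
#' @return Nested list keyed by condition plus `reliability`,
#'   `anthropometry` and `demographics`.
#' @export
run_stats_battery <- function(trials, cohort) {
  out <- list()
  all_fits <- list()
  for (cn in unique(trials$condition)) {
    d <- trials[trials$condition == cn, ]
    res <- list()
    res$lmm_csa <- fit_lmm(d, "csa")
    res$lmm_jva <- fit_lmm(d, "jva")
    res$lmm_jva_adj <- fit_lmm(d, "jva", covariate_baseline_csa = TRUE)
    res$rmcorr <- lapply(split(d, d$sex), function(s) {
      tryCatch(suppressWarnings(rmcorr(s)), error = function(e) NULL)
    })
    fits <- individual_fits(d)
    fits$condition <- cn
    all_fits[[cn]] <- fits
    res$fits <- fits
    res$fit_summary <- summarise_fits(fits)
    res$slope_test <- compare_slopes(fits$slope[fits$sex == "M"],
                                     fits$slope[fits$sex == "F"])
    out[[cn]] <- res
  }
  pooled <- do.call(rbind, all_fits)
  out$reliability <- stratify_reliability(pooled)
  baseline <- trials[trials$condition == "HDT" & trials$level == 0, ]
  out$anthropometry <- anthropometric_correlations(baseline, cohort)
  out$demographics <- demographics_tests(cohort[cohort$id %in% trials$participant, ])
  out
}

#' Generate small fixtures for unit tests
#'
#' A 16 x 16 x `n_frames` scene with the same structure as the full-scale
#' default (reflectance target, midline, vessel strip, artery strip), with
#' known ground truth, written as TIFF + sidecar CSV.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param n_frames Frames to render (default 120 at 30 Hz).
#' @return List: `paths` (tiff/sidecar), `scene`, `participant`, `dynamics`,
#'   `stack`, `config`.
#' @export
make_fixtures <- function(seed, dir = tempdir(), n_frames = 120L) {
  config <- fixture_config()
  cohort <- make_cohort(1, 1, seed, config)
  p <- cohort[1, ]
  # scale the vessel to the 0.8 cm fixture field of view
  p$csa_baseline <- 0.07
  p$hdt_delta <- 0.03
  scene <- build_scene(p, config)
  fs <- 30
  dyn <- render_dynamics(p, "HDT", 0, n_frames / fs, fs,
                         derive_seed(seed, p$id, "dynamics"))
  stack <- render_stack(scene, p, dyn, dyn$signals, config$noise, seed)
  tiff_path <- file.path(dir, "fixture_stack.tiff")
  write_stack(stack, tiff_path, dyn$signals)
  list(paths = list(tiff = tiff_path,
                    sidecar = sub("\\.tiff$", ".csv", tiff_path)),
       scene = scene, participant = p, dynamics = dyn, stack = stack,
       config = config)
}

#' Desk-scale fixture configuration (16 x 16 scene)
#' @param ... Overrides passed through to [default_config()].
#' @return Configuration list.
#' @export
fixture_config <- function(...) {
  base <- list(
    scene = list(height = 16L, width = 16L, midline_row = 6L,
                 vessel_rows = 9:16, vessel_col_center = 11,
                 artery_rows = 9:16, artery_cols = 3:4,
                 target_rows = 1:4, target_cols = 1:4),
    noise = list(enabled = FALSE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(base[[nm]])) {
      base[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      base[[nm]] <- dots[[nm]]
    }
  }
  do.call(default_config, base)
}
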