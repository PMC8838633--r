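# Simulated ultrasound CSA measurement: 5-s cine loop, post-R-spike frame
# selection, maximum CSA across ~5 cardiac cycles.

#' Simulate a 5-s ultrasound cine loop
#'
#' Ground-truth per-frame CSA at the ultrasound frame rate, generated from
#' the same vessel dynamics model as the optical pipeline (same heart, same
#' seed stream), together with the ECG R-spike times. The cardiac waveform is
#' phase-aligned so that the sample just after each R-spike sits near the
#' venous c-wave.
#'
#' @param participant Cohort row.
#' @param condition,level Condition level.
#' @param seed Integer seed (share with the optical trial for a common heart).
#' @param duration Seconds (default 5; covers >= 5 cardiac cycles at 60+ bpm).
#' @param fps Frame rate (default 23, a typical video export).
#' @param ... Passed to [render_dynamics()].
#' @return List: `csa_true` (cm2 per frame), `r_spike_times` (s), `fps`,
#'   `duration`.
#' @export
make_cineloop <- function(participant, condition, level, seed,
                          duration = 5, fps = 23, ...) {
  dyn <- render_dynamics(participant, condition, level, duration, fps, seed, ...)
  list(csa_true = dyn$csa_t, r_spike_times = dyn$signals$r_spike_times,
       fps = fps, duration = duration)
}

#' Select the frame immediately following each ECG R-spike
#'
#' Frame `k` (1-based) spans `[(k-1)/fps, k/fps)`; a spike at time `s` lies in
#' frame `floor(s*fps) + 1`, and the frame immediately following it is
#' `floor(s*fps) + 2` - never the spike's own frame. Spikes whose following
#' frame falls beyond the loop are dropped; duplicate indices collapse.
#'
#' @param loop Cine loop from [make_cineloop()].
#' @return Sorted integer vector of 1-based frame indices.
#' @export
select_post_rspike_frames <- function(loop) {
  if (length(loop$r_spike_times) < 1) stop("no R-spikes within the loop")
  idx <- floor(loop$r_spike_times * loop$fps) + 2L
  idx <- sort(unique(idx[idx <= length(loop$csa_true)]))
  if (length(idx) == 0) stop("no post-spike frames fall within the loop")
  idx
}

#' Measure CSA from a cine loop
#'
#' Semi-automatic ellipse tracing on B-mode frames is replaced by ground
#' truth plus Gaussian operator noise (truncated positive). The measurement
#' is the maximum CSA across the post-R-spike frames of the loop (~5 cardiac
#' cycles), which suppresses respiratory variability.
#'
#' @param loop Cine loop from [make_cineloop()].
#' @param noise_sd Operator/tracing noise sd in cm2 (>= 0).
#' @param seed Integer seed.
#' @return List: `value` (cm2), `n_cycles_used`.
#' @export
measure_csa <- function(loop, noise_sd = 0.02, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  idx <- select_post_rspike_frames(loop)
  set.seed(derive_seed(seed, "ultrasound"))
  vals <- loop$csa_true[idx] + stats::rnorm(length(idx), 0, noise_sd)
  while (any(vals <= 0)) {  # truncate the noise at positive area
    bad <- vals <= 0
    vals[bad] <- loop$csa_true[idx][bad] + stats::rnorm(sum(bad), 0, noise_sd)
  }
  list(value = max(vals), n_cycles_used = length(idx))
}
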