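# Reference signals: finger photoplethysmogram and ECG R-spike times.

# Canonical pulse shape on beat phase [0, 1): systolic peak followed by a
# dicrotic bump. Arbitrary units, non-negative.
pulse_shape <- function(phi) {
  exp(-(phi - 0.18)^2 / (2 * 0.08^2)) + 0.4 * exp(-(phi - 0.47)^2 / (2 * 0.13^2))
}

#' Generate a synthetic finger PPG with ECG R-spike times
#'
#' Quasi-periodic arterial pulse waveform with Gaussian cycle-length jitter.
#' Each R-spike precedes the PPG systolic upstroke of its beat by a fixed
#' pulse-transit offset, mirroring a time-synchronized finger probe. With
#' zero jitter the waveform is exactly periodic at `heart_rate/60` Hz.
#'
#' @param heart_rate Beats per minute.
#' @param duration Seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param jitter_sd Relative sd of the per-beat period (truncated at 3 sd).
#' @param ptt Pulse transit offset from R-spike to PPG beat onset, seconds.
#' @return List: `ppg` (length `duration*fs`, a.u.), `r_spike_times`
#'   (seconds, within `[0, duration)`), `fs`, `duration`.
#' @export
generate_ppg <- function(heart_rate, duration, fs, seed,
                         jitter_sd = 0.03, ptt = 0.2) {
  stopifnot(heart_rate > 0, duration > 0, fs > 0)
  set.seed(derive_seed(seed, "ppg"))
  period <- 60 / heart_rate
  n_beats <- ceiling((duration + 2 * period + ptt) / period) + 2
  eps <- pmin(pmax(stats::rnorm(n_beats, 0, jitter_sd), -3 * jitter_sd), 3 * jitter_sd)
  periods <- period * (1 + eps)
  # first R-spike shortly after t = 0, one virtual beat before it
  r_all <- 0.1 + c(-periods[1], 0, cumsum(periods[-1]))
  onsets <- r_all + ptt
  nT <- round(duration * fs)
  t <- (seq_len(nT) - 1) / fs
  # epsilon guards against sample times landing exactly on a beat onset
  k <- findInterval(t + 1e-9, onsets)
  k[k < 1] <- 1
  phi <- (t - onsets[k]) / (onsets[pmin(k + 1, length(onsets))] - onsets[k])
  list(ppg = pulse_shape(phi),
       r_spike_times = r_all[r_all >= 0 & r_all < duration],
       fs = fs, duration = duration)
}
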