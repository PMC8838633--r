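# Scene model: spatial layout of the lateral neck as seen by the camera.
#
# Coordinates are 1-based matrix indices, row 1 = superior. "Inferior from the
# midline" means rows > midline_row. The internal jugular vein runs along the
# image rows (cranio-caudal axis) at a fixed column; the carotid artery is a
# thin parallel strip; a flexible reflectance target of known reflectance sits
# in the superior-left corner, aligned to the 4x4 down-sampling grid.

#' Build the optical scene for one participant
#'
#' Vessel distension is modelled as an ellipse with fixed lateral half-width
#' `w` and CSA-proportional anteroposterior height `h = CSA / (pi * w)`:
#' compliant veins flatten and re-round rather than widen, so the lateral
#' footprint seen by the camera is constant while the two-pass (reflection
#' mode) optical path through blood at lateral offset `dx` is
#' `L(dx) = 4 h sqrt(1 - (dx/w)^2)`. Integrated over the footprint this makes
#' the region-mean blood attenuation exactly linear in CSA.
#'
#' The half-width is sized from the participant's maximum CSA (baseline +
#' head-down-tilt response + pulsatile headroom) so the ellipse never exceeds
#' circular. The per-participant blood absorptivity `mu_blood` is solved so
#' that the participant's attenuation-vs-CSA slope over the ground-truth
#' down-sampled vessel footprint equals `jva_gain` at the anchor hemoglobin
#' scale and vessel depth; the participant's actual hemoglobin and depth then
#' modulate the realized slope through the Beer-Lambert forward model.
#'
#' @param participant One cohort row (see [make_cohort()]).
#' @param config Configuration list, see [default_config()].
#' @return A scene list: dimensions, pixel pitch (cm/px), `midline_row`,
#'   `unit_L` (HxW blood path length per unit CSA, cm per cm2), logical masks
#'   `vessel_mask`, `artery_mask`, `target_mask`, the down-sampled ground
#'   truth `vessel_mask_ds`, `scm_map` (cm), optical constants and the
#'   derived `mu_blood`.
#' @export
build_scene <- function(participant, config = default_config()) {
  sc <- config$scene
  op <- config$optics
  H <- sc$height; W <- sc$width; pitch <- sc$pitch_cm
  dyn <- config$dynamics
  csa_ref <- (participant$csa_baseline + participant$hdt_delta) *
    (1 + dyn$cardiac_amp + dyn$resp_amp + 0.02)
  w <- sqrt(csa_ref / pi) # lateral half-width, cm

  col_x <- (seq_len(W) - 0.5) * pitch
  dx <- col_x - sc$vessel_col_center * pitch
  unit_col <- ifelse(abs(dx) < w, 4 * sqrt(pmax(1 - (dx / w)^2, 0)) / (pi * w), 0)
  unit_L <- matrix(0, H, W)
  unit_L[sc$vessel_rows, ] <- rep(unit_col, each = length(sc$vessel_rows))

  vessel_mask <- unit_L > 0
  target_mask <- matrix(FALSE, H, W)
  target_mask[sc$target_rows, sc$target_cols] <- TRUE
  artery_mask <- matrix(FALSE, H, W)
  artery_mask[sc$artery_rows, sc$artery_cols] <- TRUE
  if (any(artery_mask & vessel_mask)) stop("artery and vessel masks overlap")
  if (any(target_mask & (vessel_mask | artery_mask))) {
    stop("reflectance target overlaps tissue vasculature")
  }
  if (any(which(rowSums(vessel_mask) > 0) <= sc$midline_row)) {
    stop("vessel pixels must lie strictly inferior to the midline row")
  }

  # Ground-truth down-sampled vessel footprint: 4x4 blocks at least half
  # covered by vessel pixels.
  vessel_mask_ds <- block_fraction(vessel_mask) >= 0.5

  scm_map <- matrix(participant$scm_thickness, H, W)
  scm_map[target_mask] <- 0

  # Unit slope of footprint-mean attenuation per cm2 CSA at mu*hb*D = 1.
  s0 <- mean_over_ds_blocks(unit_L, vessel_mask_ds)
  d_ref <- exp(-op$depth_ref_cm / op$depth_delta_cm)
  mu_blood <- participant$jva_gain / (op$hb_ref * d_ref * s0)

  list(
    height = H, width = W, pitch_cm = pitch,
    midline_row = sc$midline_row, midline_row_ds = sc$midline_row %/% 4L,
    unit_L = unit_L, vessel_mask = vessel_mask, vessel_mask_ds = vessel_mask_ds,
    artery_mask = artery_mask, target_mask = target_mask, r_ref = sc$r_ref,
    scm_map = scm_map,
    mu_myo = op$mu_myo, background_mu = op$background_mu,
    depth_delta_cm = op$depth_delta_cm, hb_ref = op$hb_ref,
    depth_ref_cm = op$depth_ref_cm, i0 = op$i0,
    artery_base = op$artery_base, artery_amp = op$artery_amp,
    mu_blood = mu_blood, unit_slope = s0,
    participant_id = participant$id
  )
}

# Fraction of each 4x4 block covered by TRUE pixels; returns floor(H/4) x
# floor(W/4) matrix.
block_fraction <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  H4 <- H %/% 4L; W4 <- W %/% 4L
  m <- mask[seq_len(4 * H4), seq_len(4 * W4), drop = FALSE] * 1
  dim(m) <- c(4, H4, 4, W4)
  apply(m, c(2, 4), mean)
}

# Mean of a full-resolution field over the full-resolution pixels of the
# given down-sampled blocks.
mean_over_ds_blocks <- function(field, ds_mask) {
  idx <- which(ds_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty down-sampled mask")
  vals <- unlist(lapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    field[(4 * r - 3):(4 * r), (4 * c - 3):(4 * c)]
  }))
  mean(vals)
}

#' Realized attenuation-vs-CSA slope of a participant
#'
#' The sampled `jva_gain` anchored at the reference hemoglobin scale and
#' vessel depth, modulated by the participant's own hemoglobin and the
#' exponential depth-sensitivity kernel. This is the slope the full optical
#' pipeline realizes over the vessel footprint (a.u. per cm2).
#'
#' @param participant One cohort row.
#' @param config Configuration list.
#' @return Numeric slope(s), a.u./cm2. Vectorized over cohort rows.
#' @export
realized_slope <- function(participant, config = default_config()) {
  op <- config$optics
  participant$jva_gain * participant$hb_scale *
    exp(-participant$ijv_depth / op$depth_delta_cm) /
    (op$hb_ref * exp(-op$depth_ref_cm / op$depth_delta_cm))
}

#' Expected peak JVA for a participant at a given mean CSA
#'
#' Closed form of the rendered pipeline with noise disabled: blood term
#' (realized slope times peak instantaneous CSA), two-pass myoglobin term
#' through the sternocleidomastoid, and static background absorbance.
#'
#' @param participant Cohort row(s).
#' @param mean_csa Mean CSA in cm2.
#' @param config Configuration list.
#' @param peak_mod Peak fractional CSA excursion above the mean (cardiac +
#'   respiratory), matching the generator's modulation amplitudes.
#' @return Expected peak JVA in a.u.
#' @export
expected_peak_jva <- function(participant, mean_csa, config = default_config(),
                              peak_mod = config$dynamics$cardiac_amp +
                                config$dynamics$resp_amp) {
  realized_slope(participant, config) * mean_csa * (1 + peak_mod) +
    2 * config$optics$mu_myo * participant$scm_thickness +
    config$optics$background_mu
}
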