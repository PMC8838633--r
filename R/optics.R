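# Forward optical model: layered Beer-Lambert attenuation and camera
# rendering of the near-infrared neck video.

#' Per-pixel optical attenuation for an instantaneous CSA
#'
#' Layered Beer-Lambert model in reflection mode:
#' `A = mu_blood * hb_scale * L_blood(x, y; CSA) * D(depth)
#'    + mu_myo * L_scm(x, y) + background_mu`,
#' where `L_blood` is the two-pass path length through the vessel lumen,
#' `L_scm = 2 * sternocleidomastoid thickness` the two-pass muscle path, and
#' `D(depth) = exp(-depth / delta)` a monotone-decreasing depth-sensitivity
#' factor for light that reached the vessel. Pixels of the reflectance target
#' carry `A = -log10(R_ref)` exactly.
#'
#' @param scene Scene list from [build_scene()].
#' @param participant The cohort row the scene was built for.
#' @param csa_t Instantaneous CSA in cm2 (> 0).
#' @return HxW matrix of attenuation in a.u.
#' @export
attenuation_forward <- function(scene, participant, csa_t) {
  if (csa_t <= 0) stop("csa_t must be positive")
  D <- exp(-participant$ijv_depth / scene$depth_delta_cm)
  A <- scene$background_mu + scene$mu_myo * 2 * scene$scm_map +
    scene$mu_blood * participant$hb_scale * D * scene$unit_L * csa_t
  A[scene$target_mask] <- -log10(scene$r_ref)
  A
}

#' Render a near-infrared frame stack
#'
#' Camera model `I(x, y, t) = I0 * 10^(-A(x, y, t)) + noise`. The attenuation
#' field combines the static tissue layers, the blood term scaled by the
#' instantaneous CSA from `dynamics`, and an arterial strip modulating in
#' phase with the PPG (the venous blood term is anti-phase by construction of
#' the dynamics). Noise, when enabled, is signal-dependent shot noise
#' (variance proportional to intensity) plus additive Gaussian read noise;
#' intensities are clipped at zero.
#'
#' @param scene Scene list from [build_scene()].
#' @param participant The cohort row the scene was built for.
#' @param dynamics Vessel dynamics from [render_dynamics()].
#' @param signals Reference signals from [generate_ppg()]; must share `fs`
#'   and length with `dynamics`.
#' @param noise List with `enabled`, `shot_scale`, `read_sd`
#'   (see [default_config()]).
#' @param seed Integer seed for the noise draw.
#' @return A frame stack: list with `data` (T x H x W array of non-negative
#'   intensities), `fs`, `i0`, `height`, `width`.
#' @export
render_stack <- function(scene, participant, dynamics, signals,
                         noise = default_config()$noise, seed = 1L) {
  if (dynamics$fs != signals$fs) stop("dynamics and signals sampling rates differ")
  if (length(dynamics$csa_t) != length(signals$ppg)) {
    stop("dynamics and signals durations differ")
  }
  H <- scene$height; W <- scene$width
  nT <- length(dynamics$csa_t)

  D <- exp(-participant$ijv_depth / scene$depth_delta_cm)
  a_static <- scene$background_mu + scene$mu_myo * 2 * scene$scm_map
  a_static[scene$artery_mask] <- a_static[scene$artery_mask] + scene$artery_base
  a_static[scene$target_mask] <- -log10(scene$r_ref)
  b_blood <- scene$mu_blood * participant$hb_scale * D * scene$unit_L
  b_art <- scene$artery_amp * (scene$artery_mask * 1)

  # rank-2 temporal structure: static + blood x CSA(t) + artery x PPG(t)
  A <- as.vector(a_static) +
    as.vector(b_blood) %o% dynamics$csa_t +
    as.vector(b_art) %o% normalize_unit(signals$ppg)
  I <- scene$i0 * 10^(-A)
  if (isTRUE(noise$enabled)) {
    set.seed(derive_seed(seed, "camera-noise"))
    # shot + read noise: independent Gaussians, drawn as one with summed variance
    I <- I + sqrt(noise$shot_scale * I + noise$read_sd^2) * stats::rnorm(length(I))
    I[I < 0] <- 0
  }
  frame_stack(t(I), H, W, dynamics$fs, scene$i0)
}

# Construct a frame stack from a T x (H*W) matrix (pixels column-major).
frame_stack <- function(m, H, W, fs, i0) {
  stopifnot(ncol(m) == H * W)
  data <- m
  dim(data) <- c(nrow(m), H, W)
  list(data = data, fs = fs, i0 = i0, height = H, width = W)
}

# View a stack's data as a T x (H*W) matrix without copying semantics issues.
stack_matrix <- function(stack) {
  m <- stack$data
  dim(m) <- c(dim(stack$data)[1], stack$height * stack$width)
  m
}

#' Write / read a frame stack as multi-page TIFF with a sidecar CSV
#'
#' One 32-bit float page per frame, intensities stored relative to `2 * i0`.
#' The sidecar CSV holds the per-sample PPG and a second block of R-spike
#' times, plus the acquisition metadata needed to reconstruct the stack.
#'
#' @param stack Frame stack from [render_stack()].
#' @param path TIFF path.
#' @param signals Optional reference signals to write alongside.
#' @param sidecar_path CSV path (defaults to `path` with `.csv`).
#' @return `read_stack()` returns a list with `stack` and (if present)
#'   `signals`.
#' @export
write_stack <- function(stack, path, signals = NULL,
                        sidecar_path = sub("\\.tiff?$", ".csv", path)) {
  nT <- dim(stack$data)[1]
  scale <- 2 * stack$i0
  pages <- lapply(seq_len(nT), function(t) {
    pmin(pmax(stack$data[t, , ] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  meta <- data.frame(key = c("fs", "i0", "scale", "height", "width"),
                     value = c(stack$fs, stack$i0, scale, stack$height, stack$width))
  utils::write.csv(meta, sidecar_path, row.names = FALSE)
  if (!is.null(signals)) {
    utils::write.csv(data.frame(ppg = signals$ppg),
                     sub("\\.csv$", "_ppg.csv", sidecar_path), row.names = FALSE)
    utils::write.csv(data.frame(r_spike_times = signals$r_spike_times),
                     sub("\\.csv$", "_rspikes.csv", sidecar_path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, sidecar_path = sub("\\.tiff?$", ".csv", path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- utils::read.csv(sidecar_path)
  mv <- stats::setNames(meta$value, meta$key)
  H <- as.integer(mv["height"]); W <- as.integer(mv["width"])
  m <- t(vapply(pages, as.vector, numeric(H * W))) * mv[["scale"]]
  out <- list(stack = frame_stack(m, H, W, mv[["fs"]], mv[["i0"]]))
  ppg_path <- sub("\\.csv$", "_ppg.csv", sidecar_path)
  rs_path <- sub("\\.csv$", "_rspikes.csv", sidecar_path)
  if (file.exists(ppg_path) && file.exists(rs_path)) {
    out$signals <- list(ppg = utils::read.csv(ppg_path)$ppg,
                        r_spike_times = utils::read.csv(rs_path)$r_spike_times,
                        fs = mv[["fs"]])
  }
  out
}
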