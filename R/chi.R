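# CHI processing chain: down-sample, calibrate to attenuation, denoise,
# localize the jugular vein by PPG anticorrelation, extract peak JVA.

#' 4x4 mean pixel down-sampling
#'
#' Each output pixel is the arithmetic mean of its 4x4 input block, computed
#' per frame; trailing rows/columns that do not fill a block are dropped.
#' Averaging 16 i.i.d. pixels cuts uncorrelated noise by a factor 4.
#'
#' @param stack Frame stack (see [render_stack()]).
#' @return Down-sampled frame stack with dimensions `floor(H/4) x floor(W/4)`.
#' @export
downsample_4x4 <- function(stack) {
  d <- dim(stack$data)
  nT <- d[1]; H <- d[2]; W <- d[3]
  if (H < 4 || W < 4) stop("frame smaller than 4x4 cannot be down-sampled")
  H4 <- H %/% 4L; W4 <- W %/% 4L
  a <- stack$data[, seq_len(4 * H4), seq_len(4 * W4), drop = FALSE]
  dim(a) <- c(nT, 4, H4, 4, W4)
  a <- aperm(a, c(2, 4, 1, 3, 5))
  dim(a) <- c(16, nT * H4 * W4)
  m <- colMeans(a)
  dim(m) <- c(nT, H4 * W4)
  frame_stack(m, H4, W4, stack$fs, stack$i0)
}

# Map full-resolution pixel coordinates (2-col matrix) to the unique
# down-sampled block coordinates they fall in.
ds_coords <- function(pixels) {
  unique(cbind((pixels[, 1] - 1L) %/% 4L + 1L, (pixels[, 2] - 1L) %/% 4L + 1L))
}

#' Calibrate intensities to optical attenuation
#'
#' Uses the flexible reflectance target: per frame the incident intensity is
#' estimated as `I0_hat = mean(I[target]) / R_ref`, and attenuation is
#' `A = -log10(I / I0_hat)`. Non-positive intensities (possible under heavy
#' noise) become `NA` and are excluded from downstream validity masks.
#'
#' @param stack Frame stack at any resolution.
#' @param target_pixels 2-column matrix (row, col) of target pixels in the
#'   stack's own resolution.
#' @param r_ref Known target reflectance in (0, 1].
#' @return Attenuation stack: list with `data` (T x H x W, a.u.), `fs`.
#' @export
calibrate_attenuation <- function(stack, target_pixels, r_ref) {
  stopifnot(r_ref > 0, r_ref <= 1)
  if (is.null(dim(target_pixels))) target_pixels <- matrix(target_pixels, ncol = 2)
  if (nrow(target_pixels) == 0) stop("empty target region")
  H <- stack$height; W <- stack$width
  if (any(target_pixels[, 1] < 1 | target_pixels[, 1] > H |
          target_pixels[, 2] < 1 | target_pixels[, 2] > W)) {
    stop("target pixels outside frame bounds")
  }
  m <- stack_matrix(stack)
  cols <- target_pixels[, 1] + H * (target_pixels[, 2] - 1L)
  i0_hat <- rowMeans(m[, cols, drop = FALSE]) / r_ref
  if (any(i0_hat <= 0)) stop("non-positive target intensities: cannot calibrate")
  A <- -log10(sweep(m, 1, i0_hat, "/"))
  A[m <= 0] <- NA_real_
  dim(A) <- c(nrow(m), H, W)
  list(data = A, fs = stack$fs, height = H, width = W)
}

#' Local-level Kalman temporal denoiser
#'
#' Scalar linear Kalman filter with a random-walk (local-level) state per
#' pixel: predict `x_t = x_{t-1}` with process variance `process_var`, update
#' against the measurement with variance `meas_var`. For stationary input the
#' output variance never exceeds the input variance; as `meas_var -> 0` the
#' filter trusts the data fully and returns the input. Missing samples are
#' carried through by prediction alone.
#'
#' @param series Numeric vector, or T x P matrix filtering each column
#'   independently.
#' @param process_var Process (state innovation) variance, >= 0.
#' @param meas_var Measurement variance, > 0.
#' @return Denoised object of the same shape.
#' @export
kalman_denoise <- function(series, process_var = 1e-5, meas_var = 1e-4) {
  if (meas_var <= 0) stop("meas_var must be positive")
  if (process_var < 0) stop("process_var must be non-negative")
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  nT <- nrow(x); P <- ncol(x)
  out <- x
  state <- x[1, ]
  state[is.na(state)] <- 0
  v <- rep(meas_var, P)
  for (t in seq_len(nT)) {
    vp <- v + process_var
    z <- x[t, ]
    ok <- !is.na(z)
    k <- vp / (vp + meas_var)
    state[ok] <- state[ok] + k[ok] * (z[ok] - state[ok])
    v[ok] <- (1 - k[ok]) * vp[ok]
    v[!ok] <- vp[!ok]
    out[t, ] <- state
  }
  if (is.matrix(series)) out else drop(out)
}

# Band-pass a signal to the cardiac band with a zero-phase Butterworth filter.
bandpass_cardiac <- function(x, fs, band = c(0.7, 3.0)) {
  ny <- fs / 2
  band <- c(max(band[1], 0.01), min(band[2], 0.95 * ny))
  bf <- signal::butter(2, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Pixel-wise correlation map against the PPG
#'
#' Pearson correlation of each pixel's attenuation time series against the
#' (typically band-passed) arterial PPG. Arterial pixels correlate positively,
#' venous pixels negatively. Pixels with undefined variance or missing samples
#' are excluded from the validity mask.
#'
#' @param atten Attenuation stack from [calibrate_attenuation()] (optionally
#'   denoised).
#' @param ppg Numeric vector of the same length as the stack.
#' @return List: `r` (H x W Pearson r, `NA` where invalid), `valid_mask`.
#' @export
correlation_map <- function(atten, ppg) {
  d <- dim(atten$data)
  nT <- d[1]
  if (length(ppg) != nT) stop("PPG length does not match stack")
  if (nT < 30) stop("need at least 30 frames for a correlation map")
  m <- atten$data
  dim(m) <- c(nT, d[2] * d[3])
  valid <- colSums(is.na(m)) == 0
  sds <- rep(0, ncol(m))
  sds[valid] <- apply(m[, valid, drop = FALSE], 2, stats::sd)
  valid <- valid & sds > 0
  r <- rep(NA_real_, ncol(m))
  if (any(valid)) {
    pc <- ppg - mean(ppg)
    mc <- sweep(m[, valid, drop = FALSE], 2, colMeans(m[, valid, drop = FALSE]))
    r[valid] <- as.vector(crossprod(mc, pc)) /
      (sqrt(colSums(mc^2)) * sqrt(sum(pc^2)))
  }
  list(r = matrix(r, d[2], d[3]), valid_mask = matrix(valid, d[2], d[3]))
}

# Connected-component labelling on a logical matrix (breadth-first search).
# connectivity 4 or 8. Returns an integer matrix of labels (0 = background).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nl <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nl <- nl + 1L
    queue <- start
    lab[start] <- nl
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- (p - 1L) %% H + 1L
      pc <- (p - 1L) %/% H + 1L
      nr <- pr + offs[, 1]; nc <- pc + offs[, 2]
      ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
      np <- nr[ok] + (nc[ok] - 1L) * H
      np <- np[mask[np] & lab[np] == 0L]
      lab[np] <- nl
      queue <- c(queue, np)
    }
  }
  lab
}

#' Localize the jugular vein region of interest
#'
#' Thresholds the correlation map at `r < r_threshold` (inverse correlation
#' with the arterial pulse), restricts to rows strictly inferior to the
#' midline, labels connected components, and returns the largest; ties break
#' to the component containing the smallest row-major top-left coordinate.
#' The extent along the vessel (row) axis is capped at `max_extent_px`
#' centered on the component centroid, approximating a ~1 cm vessel segment.
#'
#' @param cmap Correlation map from [correlation_map()].
#' @param midline_row Midline row index in the map's resolution; inferior
#'   means rows `> midline_row`.
#' @param r_threshold Inverse-correlation threshold (default -0.3).
#' @param connectivity 8 (default, diagonals count) or 4.
#' @param max_extent_px Optional cap on ROI row extent, in pixels.
#' @return List with `pixels` (n x 2 matrix of row, col) and `area_px`, or
#'   `NULL` when no pixel qualifies (the caller drops the trial).
#' @export
localize_ijv <- function(cmap, midline_row, r_threshold = -0.3,
                         connectivity = 8L, max_extent_px = NULL) {
  H <- nrow(cmap$r)
  if (midline_row < 0 || midline_row >= H) stop("midline_row out of bounds")
  mask <- !is.na(cmap$r) & cmap$r < r_threshold
  if (midline_row >= 1) mask[seq_len(midline_row), ] <- FALSE
  if (!any(mask)) return(NULL)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest row-major top-left coordinate
    keys <- vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      min((idx[, 1] - 1L) * ncol(mask) + idx[, 2])
    }, numeric(1))
    best <- best[which.min(keys)]
  }
  px <- which(lab == best, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  if (!is.null(max_extent_px) && diff(range(px[, 1])) + 1L > max_extent_px) {
    ctr <- round(mean(px[, 1]))
    lo <- ctr - (max_extent_px - 1L) %/% 2L
    hi <- lo + max_extent_px - 1L
    keep <- px[, 1] >= lo & px[, 1] <= hi
    px <- px[keep, , drop = FALSE]
    # re-extract the largest connected piece within the capped band
    sub <- matrix(FALSE, H, ncol(mask))
    sub[px] <- TRUE
    lab2 <- label_components(sub, connectivity)
    sizes2 <- tabulate(lab2[lab2 > 0L])
    px <- which(lab2 == which.max(sizes2), arr.ind = TRUE)
    colnames(px) <- c("row", "col")
  }
  list(pixels = px, area_px = nrow(px))
}

#' Extract the JVA series and its peak over a region of interest
#'
#' JVA at each frame is the mean attenuation over the ROI; the peak across
#' the acquisition is the analysis value (taking the peak suppresses
#' respiratory variability). An optional moving-average window can smooth the
#' series first (default: none).
#'
#' @param atten Attenuation stack.
#' @param roi ROI from [localize_ijv()].
#' @param smooth_window Moving-average length in frames (0 or 1 = none).
#' @return List: `series` (a.u. per frame), `peak` (max of series),
#'   `area_px`.
#' @export
extract_jva <- function(atten, roi, smooth_window = 0L) {
  if (is.null(roi) || roi$area_px == 0) stop("empty ROI")
  d <- dim(atten$data)
  H <- d[2]
  if (any(roi$pixels[, 1] > H | roi$pixels[, 2] > d[3])) {
    stop("ROI outside stack bounds")
  }
  m <- atten$data
  dim(m) <- c(d[1], d[2] * d[3])
  cols <- roi$pixels[, 1] + H * (roi$pixels[, 2] - 1L)
  series <- rowMeans(m[, cols, drop = FALSE])
  if (smooth_window > 1) {
    series <- as.numeric(stats::filter(series, rep(1 / smooth_window, smooth_window)))
  }
  list(series = series, peak = max(series, na.rm = TRUE), area_px = roi$area_px)
}

#' Run the full CHI extraction chain on one acquisition
#'
#' Down-sample 4x4, calibrate to attenuation against the reflectance target,
#' denoise each pixel with the local-level Kalman filter, band-pass the PPG to
#' the cardiac band, build the anticorrelation map, localize the jugular ROI
#' inferior to the midline and extract the peak JVA.
#'
#' @param stack Full-resolution frame stack.
#' @param ppg PPG vector sampled at the stack frame rate.
#' @param scene Scene list (for target region, reflectance and midline).
#' @param config Configuration list (`chi` block controls thresholds and
#'   filter gains).
#' @return List: `jva` (see [extract_jva()]), `roi`, `cmap`, `atten`;
#'   or `NULL` when no venous ROI is found.
#' @export
chi_extract <- function(stack, ppg, scene, config = default_config()) {
  ch <- config$chi
  ds <- downsample_4x4(stack)
  target_ds <- ds_coords(which(scene$target_mask, arr.ind = TRUE))
  atten <- calibrate_attenuation(ds, target_ds, scene$r_ref)
  m <- atten$data
  dim(m) <- c(dim(atten$data)[1], ds$height * ds$width)
  m <- kalman_denoise(m, ch$kalman_process_var, ch$kalman_meas_var)
  dim(m) <- dim(atten$data)
  atten$data <- m
  bp <- bandpass_cardiac(ppg, stack$fs, ch$cardiac_band_hz)
  cmap <- correlation_map(atten, bp)
  cap <- ceiling(ch$roi_max_extent_cm / (4 * scene$pitch_cm))
  roi <- localize_ijv(cmap, scene$midline_row_ds, ch$r_threshold,
                      ch$connectivity, cap)
  if (is.null(roi)) return(NULL)
  list(jva = extract_jva(atten, roi, ch$smooth_window), roi = roi,
       cmap = cmap, atten = atten)
}
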