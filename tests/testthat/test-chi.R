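# CHI extraction chain: down-sampling, calibration, denoising, correlation
# mapping, ROI localization and JVA extraction.

test_that("4x4 down-sampling is the exact block mean and drops partial blocks", {
  a <- array(5, dim = c(3, 8, 8))
  ds <- downsample_4x4(as_stack(a))
  expect_equal(dim(ds$data), c(3, 2, 2))
  expect_true(all(ds$data == 5))
  b <- array(0, dim = c(1, 4, 4))
  b[1, , ] <- matrix(1:16, 4, 4)
  expect_equal(as.vector(downsample_4x4(as_stack(b))$data), 8.5)
  # trailing rows/cols that do not fill a block are dropped
  cc <- array(1, dim = c(2, 10, 9))
  expect_equal(dim(downsample_4x4(as_stack(cc))$data), c(2, 2, 2))
  expect_error(downsample_4x4(as_stack(array(1, dim = c(2, 3, 8)))), "4x4")
})

test_that("down-sampling reduces i.i.d. noise by the 16-pixel averaging law", {
  set.seed(42)
  a <- array(rnorm(50 * 32 * 32), dim = c(50, 32, 32))
  ds <- downsample_4x4(as_stack(a))
  expect_equal(sd(ds$data), 0.25, tolerance = 0.03)
})

test_that("Kalman filter honours its limiting behaviours and guards", {
  x <- sin(seq(0, 10, length.out = 200))
  expect_equal(kalman_denoise(x, 1e-5, 1e-12), x, tolerance = 1e-6)
  const <- rep(2.5, 100)
  expect_equal(kalman_denoise(const, 1e-5, 1e-4), const, tolerance = 1e-8)
  expect_error(kalman_denoise(x, 1e-5, 0), "meas_var")
  expect_error(kalman_denoise(x, -1, 1e-4), "process_var")
})

test_that("Kalman filter reduces MSE of a noisy cardiac-band sinusoid at default gains", {
  set.seed(7)
  t <- seq(0, 30, by = 1 / 60)
  truth <- 0.01 * sin(2 * pi * 1.2 * t)
  mses <- replicate(10, {
    noisy <- truth + rnorm(length(t), 0, 0.01)
    den <- kalman_denoise(noisy)
    c(mean((noisy - truth)^2), mean((den - truth)^2))
  })
  expect_true(all(mses[2, ] < mses[1, ]))
})

test_that("attenuation calibration inverts the known forward relation", {
  # frame at exactly the incident intensity -> zero attenuation
  a <- array(100, dim = c(5, 8, 8))
  st <- as_stack(a)
  target <- cbind(1:2, 1)
  cal <- calibrate_attenuation(st, target, 1.0)
  expect_true(all(abs(cal$data) < 1e-12))
  # intensity at 10% of incident -> attenuation 1.0
  a2 <- array(10, dim = c(2, 8, 8))
  a2[, 1:2, 1] <- 100
  cal2 <- calibrate_attenuation(as_stack(a2), target, 1.0)
  expect_equal(cal2$data[1, 5, 5], 1.0, tolerance = 1e-12)
  # a reflectance target below unity raises the incident estimate
  a3 <- array(95, dim = c(1, 8, 8))
  cal3 <- calibrate_attenuation(as_stack(a3), target, 0.95)
  expect_equal(cal3$data[1, 5, 5], -log10(0.95), tolerance = 1e-12)
  expect_error(calibrate_attenuation(as_stack(array(0, dim = c(1, 8, 8))), target, 1),
               "non-positive")
  # non-positive pixels are masked, not propagated
  a4 <- array(50, dim = c(1, 8, 8)); a4[1, 4, 4] <- 0
  expect_true(is.na(calibrate_attenuation(as_stack(a4), target, 1)$data[1, 4, 4]))
})

test_that("correlation map hits the exact endpoints and excludes degenerate pixels", {
  nT <- 200
  ppg <- sin(seq(0, 20, length.out = nT)) + rnorm(nT, 0, 0.01)
  a <- array(0, dim = c(nT, 2, 2))
  a[, 1, 1] <- ppg
  a[, 2, 1] <- -ppg
  a[, 1, 2] <- 3            # constant: undefined variance
  a[, 2, 2] <- rnorm(nT)
  cm <- correlation_map(list(data = a, fs = 30), ppg)
  expect_equal(cm$r[1, 1], 1, tolerance = 1e-12)
  expect_equal(cm$r[2, 1], -1, tolerance = 1e-12)
  expect_false(cm$valid_mask[1, 2])
  expect_true(is.na(cm$r[1, 2]))
  expect_error(correlation_map(list(data = a, fs = 30), ppg[-1]), "length")
  expect_error(correlation_map(list(data = a[1:10, , , drop = FALSE], fs = 30),
                               ppg[1:10]), "30 frames")
})

test_that("white-noise pixels almost never exceed |r| = 0.1 at 1800 frames", {
  set.seed(11)
  nT <- 1800
  ppg <- sin(seq(0, 180, length.out = nT))
  a <- array(rnorm(nT * 20 * 25), dim = c(nT, 20, 25))
  cm <- correlation_map(list(data = a, fs = 60), ppg)
  expect_gte(mean(abs(cm$r) < 0.1), 0.99)
})

test_that("ROI localization honours size, midline and containment rules", {
  r <- matrix(0, 12, 12)
  mk <- function(r) list(r = r, valid_mask = !is.na(r))
  # single anticorrelated blob below the midline is recovered exactly
  r1 <- r; r1[8:10, 3:5] <- -0.8
  roi <- localize_ijv(mk(r1), midline_row = 6)
  expect_equal(roi$area_px, 9)
  expect_setequal(paste(roi$pixels[, 1], roi$pixels[, 2]),
                  paste(rep(8:10, 3), rep(3:5, each = 3)))
  # larger of two blobs wins
  r2 <- r; r2[8:9, 1:5] <- -0.9; r2[11:12, 8:12] <- -0.9; r2[11, 10] <- 0
  roi2 <- localize_ijv(mk(r2), 6)
  expect_equal(roi2$area_px, 10)
  expect_true(all(roi2$pixels[, 1] %in% 8:9))
  # blob above the midline only -> explicit no-ROI signal
  r3 <- r; r3[1:3, 1:3] <- -0.9
  expect_null(localize_ijv(mk(r3), 6))
  # threshold is strict
  r4 <- r; r4[8, 8] <- -0.3
  expect_null(localize_ijv(mk(r4), 6))
  expect_error(localize_ijv(mk(r), 40), "midline_row")
})

test_that("tie-break and connectivity behave deterministically", {
  r <- matrix(0, 12, 12)
  mk <- function(r) list(r = r, valid_mask = !is.na(r))
  # equal-size blobs: the smaller row-major top-left coordinate wins
  r1 <- r; r1[9:10, 9:10] <- -0.9; r1[8:9, 2:3] <- -0.9
  roi <- localize_ijv(mk(r1), 6)
  expect_true(all(roi$pixels[, 2] %in% 2:3))
  # diagonal neighbours merge under 8- but not 4-connectivity
  r2 <- r; r2[8, 3] <- -0.9; r2[9, 4] <- -0.9; r2[10, 5] <- -0.9
  expect_equal(localize_ijv(mk(r2), 6, connectivity = 8L)$area_px, 3)
  expect_equal(localize_ijv(mk(r2), 6, connectivity = 4L)$area_px, 1)
  # row extent cap keeps a centered band
  r3 <- r; r3[7:12, 5] <- -0.9
  roi3 <- localize_ijv(mk(r3), 6, max_extent_px = 3)
  expect_equal(roi3$area_px, 3)
  expect_equal(sort(roi3$pixels[, 1]), 9:11)
})

test_that("JVA extraction returns the ROI-mean series and its peak", {
  a <- array(0, dim = c(10, 6, 6))
  a[, 3, 3] <- 0.4
  a[, 4, 3] <- 0.6
  roi <- list(pixels = cbind(c(3, 4), c(3, 3)), area_px = 2L)
  res <- extract_jva(list(data = a), roi)
  expect_equal(res$series, rep(0.5, 10))
  expect_equal(res$peak, 0.5)
  expect_gte(res$peak, max(res$series))
  expect_error(extract_jva(list(data = a), list(pixels = cbind(99, 1), area_px = 1L)),
               "bounds")
  expect_error(extract_jva(list(data = a), NULL), "empty ROI")
})

test_that("peak JVA of a rendered sinusoidal modulation matches the analytic maximum", {
  nT <- 240
  t <- seq_len(nT)
  amod <- 0.5 + 0.08 * sin(2 * pi * t / 60)
  i0 <- 1000
  a <- array(i0, dim = c(nT, 8, 8))
  for (k in 5:6) a[, k, 5] <- i0 * 10^(-amod)
  st <- as_stack(a, i0 = i0)
  cal <- calibrate_attenuation(st, cbind(1:2, 1), 1.0)
  res <- extract_jva(cal, list(pixels = cbind(c(5, 6), c(5, 5)), area_px = 2L))
  expect_equal(res$peak, max(amod), tolerance = 1e-9)
})

test_that("full chain localizes the vessel and rejects the artery at zero noise", {
  fx <- make_fixtures(5, n_frames = 150L)
  res <- chi_extract(fx$stack, fx$dynamics$signals$ppg, fx$scene, fx$config)
  gt <- which(fx$scene$vessel_mask_ds, arr.ind = TRUE)
  keys <- function(m) paste(m[, 1], m[, 2])
  # ROI covers the (half-covered-block) ground truth footprint...
  expect_true(all(keys(gt) %in% keys(res$roi$pixels)))
  # ...and never strays outside blocks touched by the vessel
  touched <- unique(cbind((which(fx$scene$vessel_mask, arr.ind = TRUE)[, 1] - 1) %/% 4 + 1,
                          (which(fx$scene$vessel_mask, arr.ind = TRUE)[, 2] - 1) %/% 4 + 1))
  expect_true(all(keys(res$roi$pixels) %in% keys(touched)))
  # arterial blocks correlate positively and never enter the ROI
  art <- unique(cbind((which(fx$scene$artery_mask, arr.ind = TRUE)[, 1] - 1) %/% 4 + 1,
                      (which(fx$scene$artery_mask, arr.ind = TRUE)[, 2] - 1) %/% 4 + 1))
  art <- art[!keys(art) %in% keys(touched), , drop = FALSE]
  expect_true(all(res$cmap$r[art] > 0))
  expect_false(any(keys(art) %in% keys(res$roi$pixels)))
  unlink(unlist(fx$paths))
})
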