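test_that("background subtraction removes the mean spectrum and is idempotent", {
  cfg <- quiet_cfg(n_pixels = 256, n_ascans = 8, seed = 2, read_std = 1,
                   depth_jitter_um = 1)
  cfg$dc_level <- 2
  fr <- simulate_frame(make_phantom("mirror", depth_um = 30),
                       gauss_src(cfg), cfg)
  out <- subtract_background(fr)
  expect_lt(max(abs(rowMeans(out$channel_H))),
            1e-10 * max(abs(fr$channel_H)))
  out2 <- subtract_background(out)
  expect_equal(out2$channel_H, out$channel_H, tolerance = 1e-12)

  # all-identical A-scans collapse to zero
  fr$channel_H <- matrix(rep(fr$channel_H[, 1], 8), ncol = 8)
  fr$channel_V <- fr$channel_H
  z <- subtract_background(fr)
  expect_equal(max(abs(z$channel_H)), 0)

  # constant + zero-mean fringe set: the fringe set survives
  n <- 256
  fringes <- matrix(rnorm(n * 8), n, 8)
  fringes <- fringes - rowMeans(fringes)
  fr$channel_H <- 100 + fringes
  fr$channel_V <- fr$channel_H
  expect_equal(subtract_background(fr)$channel_H, fringes,
               tolerance = 1e-12)
})

test_that("channel alignment remaps V by (m, c) and applies the norm curve", {
  cfg <- quiet_cfg(n_pixels = 512)
  fr <- simulate_frame(make_phantom("mirror", depth_um = 40),
                       gauss_src(cfg), cfg)
  # identity calibration
  id <- channel_calibration(1, 0, 1)
  expect_equal(align_channels(fr, id)$channel_V[50:450, ],
               fr$channel_V[50:450, ], tolerance = 1e-9)

  # a delta-like landmark moves by exactly c pixels
  fr2 <- fr
  fr2$channel_V <- matrix(0, 512, 1)
  fr2$channel_V[300, 1] <- 1
  shifted <- align_channels(fr2, channel_calibration(1, 2, 1),
                            interp = "linear")
  expect_equal(which.max(shifted$channel_V[, 1]), 298)

  # edge pixels whose source coordinate leaves the detector are zero-filled
  out <- align_channels(fr2, channel_calibration(1, 30, 1))
  expect_true(all(out$channel_V[(512 - 29):512, ] == 0))
})

test_that("calibration is recovered from landmarks and envelope ratios", {
  cfg <- quiet_cfg(n_pixels = 1024, n_ascans = 4)
  fr <- simulate_frame(make_phantom("mirror", depth_um = 40,
                                    retardance_deg = 45),
                       gauss_src(cfg), cfg)
  # identical landmarks -> identity mapping
  cal0 <- estimate_calibration(fr, c(200, 500, 800), c(200, 500, 800))
  expect_equal(cal0$slope_m, 1, tolerance = 1e-12)
  expect_equal(cal0$intercept_c, 0, tolerance = 1e-9)

  # V landmarks at 1.01 x + 3 of H's
  cal <- estimate_calibration(fr, c(200, 500, 800),
                              1.01 * c(200, 500, 800) + 3)
  expect_equal(cal$slope_m, 1.01, tolerance = 1e-9)
  expect_equal(cal$intercept_c, 3, tolerance = 1e-6)

  # constant envelope ratio 2 -> norm curve ~2 where the source is strong
  fr$channel_V <- 0.5 * fr$channel_H
  cal2 <- estimate_calibration(fr, c(200, 800), c(200, 800))
  src <- gauss_src(cfg)
  strong <- src$power > 0.1
  expect_equal(unname(stats::median(cal2$norm_curve[strong])), 2,
               tolerance = 0.05)
  expect_true(all(abs(cal2$norm_curve[src$power > 0.3] - 2) < 0.25))

  expect_error(estimate_calibration(fr, 100, 100), ">= 2 landmarks")
})

test_that("round trip: misaligned half-amplitude V realigns onto H", {
  cfg <- quiet_cfg(n_pixels = 1024, n_ascans = 2)
  fr <- simulate_frame(make_phantom("mirror", depth_um = 50,
                                    retardance_deg = 45),
                       gauss_src(cfg), cfg)
  m <- 1.01; cc <- 3
  x <- seq_len(1024)
  fr$channel_V <- apply(0.5 * fr$channel_H, 2, function(col)
    stats::spline(x, col, xout = (x - cc) / m, method = "fmm")$y)
  cal <- estimate_calibration(fr, c(250, 750), m * c(250, 750) + cc)
  out <- align_channels(fr, cal)
  mid <- 100:900
  expect_lt(max(abs(out$channel_V[mid, 1] - fr$channel_H[mid, 1])),
            0.05 * max(abs(fr$channel_H)))
})

test_that("k-resampling yields the defined uniform grid and sharpens off-grid fringes", {
  cfg <- quiet_cfg(n_pixels = 2048)
  fr <- simulate_frame(make_phantom("mirror", depth_um = 300),
                       make_source_spectrum(cfg, "rectangular"), cfg)
  kf <- resample_to_k(fr)
  expect_equal(kf$k_axis[1], 2 * pi / 700)
  expect_equal(kf$k_axis[2048], 2 * pi / 400)
  expect_lt(max(abs(diff(diff(kf$k_axis)))), 1e-9 * mean(diff(kf$k_axis)))

  # constant spectrum stays constant
  frc <- fr
  frc$channel_H <- matrix(1, 2048, 1)
  frc$channel_V <- frc$channel_H
  expect_equal(range(resample_to_k(frc)$channel_H[, 1]), c(1, 1),
               tolerance = 1e-9)

  # peak width above half max: resampled beats unresampled FFT
  width_bins <- function(M) {
    A <- Mod(stats::fft(M[, 1]))[1:1024]
    A[1:10] <- 0
    sum(A > max(A) / 2)
  }
  expect_lt(width_bins(kf$channel_H), width_bins(fr$channel_H))
  expect_lte(width_bins(kf$channel_H), 3)

  bad <- fr
  bad$wavelength_nm[5] <- bad$wavelength_nm[4]
  expect_error(resample_to_k(bad), "monotonic|increasing")
})

test_that("transform places reflectors at their depth and conserves energy", {
  for (z in c(25, 80, 150, 250, 400)) {
    cfg <- quiet_cfg(n_pixels = 2048)
    tm <- tomogram(mirror_kframe(z, cfg))
    dz <- tm$z_axis_um[2] - tm$z_axis_um[1]
    pk <- tm$z_axis_um[which.max(Mod(tm$A_H[, 1]))]
    expect_lt(abs(pk - z), dz + 1e-9)
  }
  # Parseval for the full FFT (unnormalized): sum|X|^2 = N sum|x|^2
  x <- rnorm(1024)
  expect_equal(sum(Mod(stats::fft(x))^2), 1024 * sum(x^2),
               tolerance = 1e-9)
})

test_that("reflectivity sums channel powers and is invariant to retardance and axis", {
  expect_equal(10 * log10(25 / 25), 0)  # |A_H| 3, |A_V| 4 -> R 25
  tomo <- list(A_H = matrix(3 + 0i), A_V = matrix(4 + 0i))
  class(tomo) <- "complex_tomogram"
  expect_equal(reflectivity(tomo)[1, 1], 25)

  cfg <- quiet_cfg(n_pixels = 1024)
  peaks <- c()
  for (d in seq(0, 90, 15)) {
    for (th in c(0, 40, 110)) {
      tm <- tomogram(mirror_kframe(100, cfg, retardance_deg = d,
                                   axis_deg = th))
      peaks <- c(peaks, max(reflectivity(tm)))
    }
  }
  expect_lt(diff(range(peaks)) / mean(peaks), 0.01)

  # averaging identical frames changes nothing
  tm <- tomogram(mirror_kframe(100, cfg))
  expect_equal(reflectivity(list(tm, tm, tm)), reflectivity(tm))
})

test_that("k-resampling plus transform recovers depths within one bin across the range", {
  cfg <- quiet_cfg(n_pixels = 1024)
  zmax <- max_depth_um(cfg)
  dz <- zmax / 512
  for (z in c(12, 0.25 * zmax, 0.5 * zmax, 0.88 * zmax)) {
    tm <- tomogram(mirror_kframe(z, cfg))
    pk <- tm$z_axis_um[which.max(Mod(tm$A_H[, 1]))]
    expect_lt(abs(pk - z), dz + 1e-9)
  }
})
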