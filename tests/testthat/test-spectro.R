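test_that("window sizing follows the coherence-length relation", {
  b <- window_for_resolution(550, 4, 1.37)
  expect_equal(4 * log(2) / b$fwhm_k / 1000, 4 * 1.37)  # air FWHM 5.48 um
  # doubling the target halves the k width
  b2 <- window_for_resolution(550, 8, 1.37)
  expect_equal(b2$fwhm_k, b$fwhm_k / 2)
  expect_error(window_for_resolution(550, -1), "> 0")
})

test_that("a window sized for 4 um tissue resolution delivers it on a simulated mirror", {
  cfg <- quiet_cfg(n_pixels = 2048)
  kf <- mirror_kframe(150, cfg, make_source_spectrum(cfg, "rectangular"))
  for (cn in c(460, 550, 640)) {
    tw <- band_reconstruct(kf, window_for_resolution(cn, 4, 1.37), pad = 4)
    expect_equal(axial_resolution(tw) / 1.37, 4, tolerance = 0.03)
  }
})

test_that("band reconstruction isolates chromatic layers and respects the grid", {
  cfg <- quiet_cfg(n_pixels = 2048)
  src <- make_source_spectrum(cfg, "rectangular")
  red_layer <- layered_sample(list(layer(120, 0.5, chroma = c(0, 0, 1))),
                              "red-only")
  kf <- resample_to_k(simulate_frame(red_layer, src, cfg))
  bl <- reflectivity(band_reconstruct(kf, window_for_resolution(460, 4),
                                      pad = 2))
  rd <- reflectivity(band_reconstruct(kf, window_for_resolution(640, 4),
                                      pad = 2))
  i <- which.max(rd)
  expect_gte(10 * log10(rd[i] / max(bl)), 20)

  # achromatic mirror: band images differ only per source power at the centers
  gs <- gauss_src(cfg)
  kfa <- mirror_kframe(120, cfg, gs)
  p460 <- max(reflectivity(band_reconstruct(kfa,
                                            window_for_resolution(460, 4),
                                            pad = 2)))
  p550 <- max(reflectivity(band_reconstruct(kfa,
                                            window_for_resolution(550, 4),
                                            pad = 2)))
  s <- function(nm) gs$power[which.min(abs(gs$wavelength_nm - nm))]
  expect_equal(p460 / p550, (s(460) / s(550))^2, tolerance = 0.05)

  expect_error(band_reconstruct(kf, window_for_resolution(405, 4)),
               "clipped")
})

test_that("band axial resolution is constant across centers by design", {
  cfg <- quiet_cfg(n_pixels = 2048)
  kf <- mirror_kframe(150, cfg, make_source_spectrum(cfg, "rectangular"))
  res <- vapply(c(460, 550, 640), function(cn)
    axial_resolution(band_reconstruct(kf, window_for_resolution(cn, 4),
                                      pad = 4)), numeric(1))
  expect_lt(diff(range(res)) / mean(res), 0.05)
})

test_that("true-color composition neutralizes identical channels and highlights red-weighted ones", {
  img <- matrix(runif(600, 0.1, 1), 30, 20)
  tc <- true_color(img, img, img)
  expect_equal(tc$rgb[, , 1], tc$rgb[, , 2])
  expect_equal(tc$rgb[, , 2], tc$rgb[, , 3])
  expect_true(all(tc$rgb >= 0 & tc$rgb <= 1))

  # mean filter leaves a constant image unchanged
  cst <- matrix(0.4, 10, 10)
  tc2 <- true_color(cst, cst, cst)
  expect_equal(range(tc2$rgb[, , 1]), rep(tc2$rgb[1, 1, 1], 2))

  # vessel phantom: red-weighted layer shows R > G and R > B
  cfg <- quiet_cfg(n_pixels = 2048, n_ascans = 8)
  src <- make_source_spectrum(cfg, "rectangular")
  kf <- resample_to_k(simulate_frame(make_phantom("vessel"), src, cfg))
  imgs <- lapply(c(460, 550, 640), function(cn)
    reflectivity(band_reconstruct(kf, window_for_resolution(cn, 4))))
  tc3 <- true_color(red = imgs[[3]], green = imgs[[2]], blue = imgs[[1]])
  tmv <- band_reconstruct(kf, window_for_resolution(640, 4))
  vz <- which.min(abs(tmv$z_axis_um - 95))
  vessel_px <- cbind(vz, seq_len(8))
  expect_true(all(tc3$rgb[, , 1][vessel_px] >= tc3$rgb[, , 2][vessel_px]))
  expect_true(all(tc3$rgb[, , 1][vessel_px] > tc3$rgb[, , 3][vessel_px]))

  expect_error(true_color(img, img[1:10, ], img), "shape")
})

test_that("en-face projection reduces depth ranges correctly", {
  vol <- matrix(seq_len(40), 8, 5)
  expect_equal(enface_project(vol, z_range = c(3, 3)), vol[3, ])
  expect_equal(enface_project(matrix(2, 6, 4)), rep(2, 4))
  arr <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  expect_equal(enface_project(arr, z_range = c(1, 8)),
               apply(arr, c(2, 3), mean))
  expect_error(enface_project(vol, z_range = c(5, 20)), "outside")
  # lesion phantom: footprint brighter in the supra-RPE projection
  cfg <- quiet_cfg(n_pixels = 2048, n_ascans = 30, seed = 2)
  ph <- make_phantom("retina_lesion", lesion_height_um = 30, n_ascans = 30)
  tm <- tomogram(resample_to_k(simulate_frame(ph, gauss_src(cfg), cfg)))
  R <- reflectivity(tm)
  zr <- range(which(tm$z_axis_um > 220 & tm$z_axis_um < 245))
  proj <- enface_project(R, z_range = zr)
  expect_gt(min(proj[11:20]), 10 * max(proj[c(1:10, 21:30)]))
})

test_that("lesion height maps recover the synthetic lesion and stay zero without one", {
  cfg <- acquisition_config(n_pixels = 2048, n_ascans = 96, read_std = 8,
                            shot_scale = 1, dc_level = 1,
                            depth_jitter_um = 1.5, seed = 5)
  src <- gauss_src(cfg)
  analyse <- function(preset, threshold_db) {
    ph <- make_phantom(preset, lesion_height_um = 30, n_ascans = 96)
    tm <- reconstruct(simulate_frame(ph, src, cfg), background = TRUE)
    R <- reflectivity(tm)
    zwin <- which(tm$z_axis_um > 240 & tm$z_axis_um < 285)
    rpe <- vapply(seq_len(ncol(R)), function(a)
      zwin[which.max(R[zwin, a])], integer(1))
    list(hm = lesion_height_map(R, rpe, tm$z_axis_um,
                                threshold_db = threshold_db,
                                max_height_um = 40),
         R = R, z = tm$z_axis_um, nf = noise_floor(R))
  }
  # boundary threshold: half maximum of the supra-RPE lesion signal
  probe <- analyse("retina_lesion", 20)
  les_win <- which(probe$z > 220 & probe$z < 240)
  thr <- 10 * log10(max(probe$R[les_win, ]) / probe$nf) - 3
  les <- analyse("retina_lesion", thr)
  dz <- les$z[2] - les$z[1]
  inside <- les$hm$height_um[33:64]
  expect_true(all(abs(inside - 30) <= dz))
  expect_true(all(les$hm$height_um[c(1:32, 65:96)] == 0))

  # same threshold on the lesion-free phantom: identically zero
  clean <- analyse("retina", thr)
  expect_true(all(clean$hm$height_um == 0))

  # raising the threshold shrinks the nonzero footprint monotonically
  n_hit <- vapply(c(thr - 15, thr - 5, thr, thr + 2.5),
                  function(t) sum(analyse("retina_lesion", t)$hm$height_um
                                  > 0), numeric(1))
  expect_true(all(diff(n_hit) <= 0))
  expect_error(lesion_height_map(les$R, rep(1e5, 96), les$z), "outside")
})

test_that("summed band images approximate the full-band image when windows tile the spectrum", {
  cfg <- quiet_cfg(n_pixels = 1024)
  kf <- mirror_kframe(100, cfg, make_source_spectrum(cfg, "rectangular"))
  k <- kf$k_axis
  # three rectangular-ish tiles emulated by wide Gaussians summing near-flat
  full <- reflectivity(tomogram(kf))
  # instead of Gaussian tiling (never exact), check the window ~= 1 case
  wide <- window_for_resolution(550, 0.05, 1.37)
  expect_error(band_reconstruct(kf, wide), "clipped")
  # additivity of the analytic decomposition: complex band profiles of two
  # half-spectrum indicator windows sum to the full profile
  xa <- analytic_env(kf$channel_H[, 1])
  lowhalf <- k <= mean(range(k))
  A_lo <- stats::fft(xa * lowhalf)[1:512]
  A_hi <- stats::fft(xa * !lowhalf)[1:512]
  A_full <- stats::fft(xa)[1:512]
  expect_equal(A_lo + A_hi, A_full, tolerance = 1e-9)
})
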