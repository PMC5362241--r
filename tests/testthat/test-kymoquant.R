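test_that("a time-constant ridge quantifies to unit normalized series", {
  k <- synth_kymograph(function(t) 4, function(t) 10,
    noise_sd = 0,
    n_frames = 30
  )
  qs <- quantify_kymograph(k, background = 1)
  expect_equal(qs$width_norm, rep(1, 30))
  expect_equal(qs$intensity_norm, rep(1, 30))
})

test_that("linear ridge broadening is recovered by the threshold width", {
  # sigma(t) = sigma0 * (1 + t/T) at fixed peak: every threshold contour
  # scales with sigma, so width_norm tracks (1 + t/T)
  Tt <- 58
  sigma0 <- 5
  k <- synth_kymograph(
    function(t) sigma0 * (1 + t / Tt), function(t) 10,
    noise_sd = 0, n_frames = 30, n_pixels = 256
  )
  qs <- quantify_kymograph(k, background = 1)
  expected <- 1 + qs$time / Tt
  expect_true(all(abs(qs$width_norm - expected) / expected < 1 / sigma0))
})

test_that("a ridge decaying below background reports zero width afterwards", {
  k <- synth_kymograph(
    function(t) 4, function(t) 10 * exp(-t / 5),
    noise_sd = 0, n_frames = 40
  )
  qs <- quantify_kymograph(k, background = 2)
  t_star <- 5 * log(10 / 2) # peak hits the background
  expect_true(all(qs$width[qs$time > t_star + 1] == 0))
  expect_true(all(qs$intensity[qs$time > t_star + 1] == 0))
  expect_true(all(qs$width[qs$time < t_star - 1] > 0))
})

test_that("generator is deterministic under a fixed seed and leaves the RNG alone", {
  k1 <- synth_kymograph(function(t) 3, function(t) 8, noise_sd = 1, seed = 7)
  k2 <- synth_kymograph(function(t) 3, function(t) 8, noise_sd = 1, seed = 7)
  expect_identical(k1$intensity, k2$intensity)
  k3 <- synth_kymograph(function(t) 3, function(t) 8, noise_sd = 1, seed = 8)
  expect_false(identical(k1$intensity, k3$intensity))
  set.seed(123)
  before <- .Random.seed
  invisible(synth_kymograph(function(t) 3, function(t) 8, noise_sd = 1, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("a prescribed 2x broadening is recovered within 10% at SNR 10", {
  Tt <- 59 # sigma doubles over the 60-frame span
  k <- synth_kymograph(
    function(t) 6 * (1 + t / Tt), function(t) 10,
    noise_sd = 1, seed = 42, n_frames = 60, n_pixels = 512, pixel_size = 0.5
  )
  qs <- quantify_kymograph(k, temporal_median = TRUE)
  broadening <- mean(tail(qs$width_norm, 3))
  expect_equal(broadening, 2, tolerance = 0.1)
})

test_that("quantification is gain- and translation-invariant", {
  k <- synth_kymograph(
    function(t) 4 * (1 + t / 100), function(t) 10,
    noise_sd = 0.5, seed = 3, n_frames = 30
  )
  qs <- quantify_kymograph(k, background = 1)
  # common positive gain on intensities and background drops out
  k2 <- k
  k2$intensity <- 7.5 * k$intensity
  qs2 <- quantify_kymograph(k2, background = 7.5)
  expect_equal(qs2$width_norm, qs$width_norm)
  expect_equal(qs2$intensity_norm, qs$intensity_norm)
  # ridge and junction translated together: widths unchanged
  drift <- seq(40, 70, length.out = 30)
  kd <- synth_kymograph(
    function(t) 4 * (1 + t / 100), function(t) 10,
    noise_sd = 0, n_frames = 30, n_pixels = 200, center = drift
  )
  qs_d <- quantify_kymograph(kd, background = 1)
  ks <- synth_kymograph(
    function(t) 4 * (1 + t / 100), function(t) 10,
    noise_sd = 0, n_frames = 30, n_pixels = 200
  )
  qs_s <- quantify_kymograph(ks, background = 1)
  # discrete sampling of the drifting centre costs at most one pixel
  expect_lt(max(abs(qs_d$width - qs_s$width)), 1 + 1e-9)
})

test_that("empty first-frame zone errors; background auto-estimate is sane", {
  k <- synth_kymograph(function(t) 3, function(t) 1, noise_sd = 0)
  expect_error(quantify_kymograph(k, background = 5), "t = 0")
  kn <- synth_kymograph(function(t) 3, function(t) 20,
    noise_sd = 0.5,
    seed = 11
  )
  bg <- estimate_background(kn)
  # clamping makes the lowest decile degenerate at 0 here; the estimate
  # must stay non-negative and well below the ridge peak
  expect_gte(bg, 0)
  expect_lt(bg, 5)
  # with a wide ridge the lowest decile picks up true tail intensity
  kw <- synth_kymograph(function(t) 40, function(t) 20, noise_sd = 0)
  expect_gt(estimate_background(kw), 0)
})

test_that("simulation records map to kymographs with the junction at the zone centre", {
  kp <- std_kp()
  g <- std_grid()
  rec <- simulate_cortex(
    make_pulse(g, high_state(kp)), kp,
    mech_params(pe = 12), g,
    t_end = 100
  )
  k <- record_to_kymograph(rec)
  expect_equal(k$junction_x[1], 20, tolerance = g$dx)
  qs <- quantify_kymograph(k, background = 0.05)
  # stationary zone: normalized width settles near a constant
  late <- tail(qs$width_norm, 20)
  expect_lt(diff(range(late)) / mean(late), 0.05)
})

test_that("kymographs round-trip through CSV and the quantification CSV matches", {
  k <- synth_kymograph(function(t) 3, function(t) 10,
    noise_sd = 0.2, seed = 5,
    n_frames = 12, n_pixels = 40
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.table(k$intensity, path,
    sep = ",", row.names = FALSE,
    col.names = FALSE
  )
  k2 <- read_kymograph(path)
  expect_equal(k2$intensity, k$intensity, tolerance = 1e-12, ignore_attr = TRUE)
  qpath <- withr::local_tempfile(fileext = ".csv")
  qs <- quantify_kymograph(k, background = 1)
  write_quant_csv(qs, qpath)
  expect_equal(read.csv(qpath)$width_norm, qs$width_norm)
})
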