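test_that("the three-pulse canceller annihilates constants and ramps", {
  p <- small_params(duration = 0.1, n_range_bins = 4)
  np <- n_pulses(p)
  const <- pulse_matrix(matrix(3.7, 4, np), p)
  expect_equal(mti_filter(const)$samples, matrix(0, 4, np - 2))
  ramp <- pulse_matrix(matrix(rep(0.5 * (1:np), each = 4), 4, np), p)
  expect_equal(mti_filter(ramp)$samples, matrix(0, 4, np - 2))
  quad <- pulse_matrix(matrix(rep((1:np)^2, each = 4), 4, np), p)
  expect_equal(mti_filter(quad)$samples, matrix(2, 4, np - 2))
  expect_equal(ncol(mti_filter(const)$samples), np - 2L)
  tiny <- pulse_matrix(matrix(1, 4, 2), p)
  expect_error(mti_filter(tiny), "at least 3 pulses")
})

test_that("the canceller's tone response matches 4 sin^2(pi f / prf)", {
  p <- radar_params(n_range_bins = 2)
  t <- slow_time_axis(p)
  for (f in c(0, p$prf / 8, p$prf / 4)) {
    X <- matrix(rep(cos(2 * pi * f * t), each = 2), 2)
    y <- mti_filter(pulse_matrix(X, p))$samples[1, ]
    amp_out <- sqrt(2 * mean(y^2))       # RMS amplitude of the output tone
    expected <- 4 * sin(pi * f / p$prf)^2
    if (f == 0) expect_equal(amp_out, 0) else
      expect_lt(abs(amp_out - expected) / expected, 0.01)
  }
})

test_that("the Hilbert envelope of a pure tone recovers its amplitude", {
  p <- radar_params(n_range_bins = 2, duration = 2)
  t <- slow_time_axis(p)
  A <- 1.8
  X <- matrix(rep(A * cos(2 * pi * 30 * t), each = 2), 2)
  env <- analytic_envelope(pulse_matrix(X, p))
  expect_s3_class(env, "radar_map")
  expect_equal(env$kind, "range_time")
  core <- env$values[1, 49:(ncol(env$values) - 48)]  # away from edges
  expect_lt(max(abs(core - A)) / A, 0.02)
  zeros <- analytic_envelope(pulse_matrix(matrix(0, 2, 240), p))
  expect_equal(zeros$values, matrix(0, 2, 240))
})

test_that("the range-time ridge tracks the simulator's known trajectory", {
  p <- radar_params()
  pr <- make_profile(7, p, rng_seed = 3)        # walking away
  pm <- synthesize_pulses(pr, p, clutter_amp = 0, noise_sigma = 0)
  rt <- analytic_envelope(mti_filter(pm))
  ridge <- apply(rt$values, 2, which.max)
  true_bins <- pmin(pmax(ceiling(
    pr$range_trajectory(rt$axis1 + 1 / p$prf) / range_resolution(p)), 1),
    p$n_range_bins)
  expect_true(all(abs(ridge - true_bins) <= 2))
  # and the oracle trajectory is increasing, so the ridge trend must be too
  expect_gt(stats::cor(ridge, seq_along(ridge)), 0.99)
})

test_that("STFT framing follows window/overlap and places tones correctly", {
  p <- radar_params(n_range_bins = 4)
  np <- n_pulses(p)
  cfg <- stft_config()
  expect_equal(cfg$window_length - cfg$overlap, 18L)
  fd <- 37.3
  tone <- exp(2i * pi * fd * slow_time_axis(p))
  X <- matrix(rep(tone, each = 4), 4)
  td <- time_doppler(pulse_matrix(X, p), cfg)
  expect_equal(ncol(td$values), (np - 128L) %/% 18L + 1L)
  peaks <- td$axis0[apply(td$values, 2, which.max)]
  expect_true(all(abs(peaks - fd) <= p$prf / cfg$window_length))
  # frequency axis spans the unambiguous interval
  expect_equal(min(td$axis0), -p$prf / 2)
  expect_equal(diff(td$axis0)[1], p$prf / 128)
  zeros <- time_doppler(pulse_matrix(matrix(0, 4, np), p), cfg)
  expect_equal(max(zeros$values), 0)
  short <- pulse_matrix(matrix(1, 4, 100), p)
  expect_error(time_doppler(short, cfg), "shorter than")
  expect_error(stft_config(overlap = 128), "overlap")
})

test_that("range-Doppler satisfies Parseval and localizes slow targets", {
  p <- radar_params(n_range_bins = 16, duration = 1)  # 240 pulses, 5-smooth
  set.seed(1)
  A <- matrix(complex(real = rnorm(16 * 240), imaginary = rnorm(16 * 240)),
              16, 240)
  rd <- range_doppler(pulse_matrix(A, p))
  expect_equal(sum(rd$values^2), 240 * sum(Mod(A)^2))
  zeros <- range_doppler(pulse_matrix(matrix(0, 16, 240), p))
  expect_equal(max(zeros$values), 0)

  # slow constant-velocity target (long dwell): peak Doppler within one bin
  # even through the clutter filter, peak range inside the traversed span
  p5 <- radar_params()
  v <- 0.3
  pm <- clean_recording(function(t) 2 + v * t, p5)
  rd5 <- range_doppler(analytic_signal(mti_filter(pm)))
  pk <- which(rd5$values == max(rd5$values), arr.ind = TRUE)
  fd <- doppler_shift(v, p5$fc)
  expect_lt(abs(rd5$axis1[pk[2]] - fd), diff(rd5$axis1)[1])
  expect_gte(rd5$axis0[pk[1]], 2 - range_resolution(p5))
  expect_lte(rd5$axis0[pk[1]], 2 + v * p5$duration + range_resolution(p5))
})

test_that("map axes recompute exactly from the radar parameters", {
  p <- radar_params()
  pm <- synthesize_pulses(make_profile(6, p, rng_seed = 1), p, rng_seed = 1)
  f <- mti_filter(pm)
  rt <- analytic_envelope(f)
  expect_identical(rt$axis0, range_axis(p))
  expect_equal(rt$axis1, (seq_len(n_pulses(p) - 2) - 1) / p$prf)
  td <- time_doppler(f)
  expect_equal(range(td$axis0), c(-p$prf / 2, p$prf / 2 - p$prf / 128))
  rd <- range_doppler(f)
  expect_identical(rd$axis0, range_axis(p))
  expect_equal(diff(rd$axis1)[1], p$prf / length(rd$axis1))
  expect_equal(sum(rd$axis1 == 0), 1L)   # zero-centred axis
})

test_that("image conversion normalizes, resamples and is scale-invariant", {
  p <- small_params()
  v <- matrix(runif(64 * 238, 0.1, 5), 64, 238)
  map <- radar_map(v, "range_time", range_axis(p), seq_len(238) / p$prf, p)
  im <- to_image(map, size = 80)
  expect_identical(dim(im$pixels), c(80L, 80L))
  expect_gte(min(im$pixels), 0)
  expect_lte(max(im$pixels), 1)
  # scaling the map magnitudes leaves the image untouched (dB + min-max)
  map10 <- radar_map(10 * v, "range_time", map$axis0, map$axis1, p)
  expect_equal(to_image(map10, 80)$pixels, im$pixels)
  # identity case: an 80 x 80 two-valued map maps to {0, 1} unchanged
  v2 <- matrix(1, 80, 80)
  v2[17, 33] <- 10
  m80 <- radar_map(v2, "range_doppler", 1:80, 1:80, p)
  im80 <- to_image(m80, 80)
  expect_equal(im80$pixels[17, 33], 1)
  expect_equal(sum(im80$pixels), 1)      # all other pixels exactly 0
  # all-zero map: documented special case, no error
  z <- radar_map(matrix(0, 10, 10), "range_doppler", 1:10, 1:10, p)
  expect_equal(to_image(z, 80)$pixels, matrix(0, 80, 80))
})

test_that("the full three-map pipeline is deterministic and labeled", {
  p <- small_params()
  pm <- synthesize_pulses(make_profile(1, p, rng_seed = 5), p, rng_seed = 5)
  a <- radar_images(pm)
  b <- radar_images(pm)
  expect_identical(names(a), c("range_time", "time_doppler", "range_doppler"))
  for (k in names(a)) {
    expect_identical(a[[k]]$pixels, b[[k]]$pixels)
    expect_identical(dim(a[[k]]$pixels), c(80L, 80L))
    expect_equal(a[[k]]$label, 1L)
  }
})
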