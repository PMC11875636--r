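fs <- 128
tgrid <- seq(0, 5 - 1 / fs, by = 1 / fs)
rms <- function(v) sqrt(mean(v^2))

test_that("band-pass filters pass in-band and reject out-of-band sinusoids", {
  x10 <- sin(2 * pi * 10 * tgrid)
  expect_gte(rms(bandpass_filter(x10, fs, band_spec("alpha", 9, 13))),
             0.95 * rms(x10))
  expect_lte(rms(bandpass_filter(x10, fs, band_spec("delta", 1, 4))),
             0.10 * rms(x10))
  expect_equal(bandpass_filter(numeric(640), fs, band_spec("theta", 4, 8)),
               numeric(640))
  expect_error(bandpass_filter(x10, fs, band_spec("bad", 60, 70)), "Nyquist")
})

test_that("filtering is linear and shape-preserving", {
  set.seed(4)
  x <- array(rnorm(4 * 3 * 320), c(4, 3, 320))
  y <- array(rnorm(4 * 3 * 320), c(4, 3, 320))
  b <- band_spec("theta", 4, 8)
  fx <- bandpass_filter(x, fs, b)
  expect_identical(dim(fx), dim(x))
  lhs <- bandpass_filter(2 * x + 3 * y, fs, b)
  expect_lt(max(abs(lhs - (2 * fx + 3 * bandpass_filter(y, fs, b)))), 1e-9)
})

test_that("zero-phase response matches the signal::filtfilt oracle", {
  set.seed(9)
  x <- rnorm(3000)                     # long enough for filtfilt's own padding
  b <- band_spec("alpha", 9, 13)
  h <- bandfocus:::.fir_design(b, fs)
  oracle <- signal::filtfilt(filt = h, a = 1, x = x)
  mine <- bandpass_filter(x, fs, b)
  core <- 800:2200
  expect_gt(stats::cor(mine[core], oracle[core]), 0.999999)
  expect_lt(max(abs(mine[core] - oracle[core])), 1e-8 * max(abs(x)))
})

test_that("band decomposition preserves order and band-limits white noise", {
  ep <- generate_subject(small_sim_config(trials_per_condition = 5), 1)
  st <- band_decompose(ep, default_bands())
  expect_equal(dim(st$data)[1], 3)
  expect_equal(dim(st$data)[-1], dim(ep$data))
  expect_error(band_decompose(ep, list()), "empty")
  # white-noise variance after filtering scales with (effective) band width
  set.seed(11)
  wn <- array(rnorm(20 * 1 * 640), c(20, 1, 640))
  v <- vapply(default_bands(), function(b)
    mean(bandpass_filter(wn, fs, b)^2), numeric(1))
  # theta (4 Hz wide) vs delta (3 Hz): ratio ~ (4+1)/(3+1) with 1 Hz transitions
  expect_gt(v[["theta"]] / v[["delta"]], 1.05)
  expect_lt(v[["theta"]] / v[["delta"]], 1.5)
  # alpha and theta share a 4 Hz width: comparable power
  expect_gt(v[["alpha"]] / v[["theta"]], 0.85)
  expect_lt(v[["alpha"]] / v[["theta"]], 1.15)
})

test_that("a near-allpass band reproduces in-band content", {
  x <- sin(2 * pi * 5 * tgrid) + 0.5 * sin(2 * pi * 12 * tgrid) +
    0.25 * sin(2 * pi * 25 * tgrid)
  wide <- band_spec("broad", 0.5, 0.9 * fs / 2)
  y <- bandpass_filter(x, fs, wide)
  core <- 100:540
  expect_lt(rms(y[core] - x[core]) / rms(x[core]), 0.05)
})

test_that("standardisation uses train-only statistics without leakage", {
  ep <- generate_subject(small_sim_config(trials_per_condition = 10), 1)
  st <- band_decompose(ep, default_bands())
  train <- 1:12
  z <- standardize_stack(st, train_trials = train)
  xs <- z$data[, train, , , drop = FALSE]
  mu <- apply(xs, c(1, 3), mean)
  va <- apply(xs, c(1, 3), function(v) stats::var(as.vector(v)))
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(va - 1)), 1e-6)
  # applying stored statistics to a shifted set must not re-center it
  st2 <- st
  st2$data <- st2$data + 5
  z2 <- standardize_stack(st2, stats = attr(z, "stats"))
  mu2 <- apply(z2$data, c(1, 3), mean)
  expect_gt(min(mu2), 1)
  # transform parameters depend only on the training trials
  st3 <- st
  st3$data[, 15:20, , ] <- st3$data[, 15:20, , ] * 100
  z3 <- standardize_stack(st3, train_trials = train)
  expect_equal(attr(z3, "stats"), attr(z, "stats"))
})

test_that("constant channels standardise without division blow-up", {
  ep <- generate_subject(small_sim_config(trials_per_condition = 3), 1)
  st <- band_decompose(ep, list(band_spec("theta", 4, 8)))
  st$data[1, , 2, ] <- 7
  expect_warning(z <- standardize_stack(st), "zero-variance")
  expect_true(all(is.finite(z$data)))
  expect_equal(unname(z$data[1, , 2, ]), array(0, dim(st$data)[c(2, 4)]),
               ignore_attr = TRUE)
})

test_that("decimation keeps band-limited content and rejects aliasing", {
  ep <- generate_subject(small_sim_config(trials_per_condition = 3), 1)
  st <- band_decompose(ep, default_bands())
  dec <- decimate_stack(st, 2)                # 64 Hz -> 32 Hz, alpha <= 13 Hz
  expect_equal(dim(dec$data)[4], dim(st$data)[4] %/% 2)
  expect_equal(dec$sampling_rate, st$sampling_rate / 2)
  expect_error(decimate_stack(st, 4), "alias")
})
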