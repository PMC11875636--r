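# build a bfn_epochs from a trials x channels x samples array
epochs_from_array <- function(arr, fs = 64, t0 = -1) {
  epochs_set("X", arr, fs, paste0("ch", seq_len(dim(arr)[2])),
             t0 + (seq_len(dim(arr)[3]) - 1) / fs,
             rep(0L, dim(arr)[1]), baseline_window = c(t0, 0))
}

test_that("stationary noise gives a flat 0 dB ERSP", {
  set.seed(21)
  fs <- 64
  arr <- array(rnorm(200 * 16 * 4 * fs), c(200, 16, 4 * fs))
  ep <- epochs_from_array(arr, fs, t0 = -1)
  m <- compute_ersp(ep, freqs = 2:30)
  expect_lt(max(abs(m$values_db[m$valid])), 0.5)
})

test_that("a planted 4x in-band power step reads ~ +6.02 dB", {
  set.seed(22)
  fs <- 64
  n <- 4 * fs
  t <- -1 + (seq_len(n) - 1) / fs
  gain <- ifelse(t >= 0, 2, 1)                  # amplitude x2 = power x4
  shape <- bandfocus:::.band_shape(n, fs, band_spec("alpha", 9, 13))
  arr <- array(0, c(120, 2, n))
  for (i in seq_len(120)) for (ch in 1:2) {
    src <- bandfocus:::.coloured_noise(n, 1, shape)[, 1]
    arr[i, ch, ] <- src * gain + 0.5 * rnorm(n)
  }
  ep <- epochs_from_array(arr, fs, t0 = -1)
  m <- compute_ersp(ep, freqs = 2:30)
  step <- roi_band_average(m, band_spec("alpha", 9, 13), c(0.5, 2.5))
  expect_lt(abs(step - 6.02), 1)
  # outside the stepped band the plane stays near 0 dB
  quiet <- roi_band_average(m, band_spec("delta", 2, 4), c(0.5, 2.5))
  expect_lt(abs(quiet), 1)
})

test_that("ERSP is invariant to global gain and uniform power scaling", {
  set.seed(23)
  fs <- 64
  arr <- array(rnorm(40 * 2 * 3 * fs), c(40, 2, 3 * fs))
  ep1 <- epochs_from_array(arr, fs)
  ep2 <- epochs_from_array(arr * 7.3, fs)       # global amplitude gain
  m1 <- compute_ersp(ep1, freqs = 2:20)
  m2 <- compute_ersp(ep2, freqs = 2:20)
  expect_equal(m1$values_db, m2$values_db, tolerance = 1e-9)
})

test_that("band/window averaging is exact and linear", {
  fs <- 64
  ep <- epochs_from_array(array(rnorm(5 * 1 * 3 * fs), c(5, 1, 3 * fs)), fs)
  m <- compute_ersp(ep, freqs = 2:20)
  m$values_db[] <- 4                            # constant map
  expect_equal(roi_band_average(m, band_spec("b", 5, 10), c(0, 1)), 4)
  # restricted selection: value only counted inside band rows/window columns
  m2 <- m
  m2$values_db[] <- 0
  m2$values_db[m$freqs >= 5 & m$freqs <= 10, ] <- 6
  expect_equal(roi_band_average(m2, band_spec("b", 5, 10), c(0, 1)), 6)
  # linearity
  ma <- m; ma$values_db <- m$values_db * 0 + 1.5
  mb <- m; mb$values_db <- m$values_db * 0 + 2.5
  msum <- m; msum$values_db <- ma$values_db + mb$values_db
  b <- band_spec("b", 3, 12); w <- c(-0.5, 1.5)
  expect_equal(roi_band_average(msum, b, w),
               roi_band_average(ma, b, w) + roi_band_average(mb, b, w))
  expect_error(roi_band_average(m, band_spec("hi", 25, 30), c(90, 99)),
               "empty")
})

test_that("synthetic conditions reproduce the frontal delta/theta dissociation", {
  cfg <- small_sim_config(trials_per_condition = 60, seed = 404)
  ep <- generate_subject(cfg, 1)
  roi <- roi_channels(cfg$montage)
  dt <- band_spec("dt", 1, 8)
  mi <- c(0.5, 2.5)
  m_nt <- compute_ersp(ep, channel_set = roi, trials = which(ep$labels == 0))
  m_st <- compute_ersp(ep, channel_set = roi, trials = which(ep$labels == 1))
  nt_db <- roi_band_average(m_nt, dt, mi)
  st_db <- roi_band_average(m_st, dt, mi)
  expect_gt(nt_db, 1)            # synchronisation present for natural thumb
  expect_lt(st_db, 1)            # absent for the supernumerary thumb
  # and the supernumerary condition desynchronises alpha at central sites
  m_sta <- compute_ersp(ep, channel_set = c("C3", "C4"),
                        trials = which(ep$labels == 1))
  expect_lt(roi_band_average(m_sta, band_spec("alpha", 9, 13), mi), -1)
})

test_that("paired bootstrap test: conventions, determinism, symmetry", {
  z <- numeric(16)
  expect_equal(bootstrap_paired_test(z, z)$p_value, 1)
  r <- bootstrap_paired_test(z + 5, z, n_boot = 2000, seed = 1)
  expect_equal(r$p_value, 1 / 2000)
  set.seed(31)
  a <- rnorm(16); b <- rnorm(16)
  r1 <- bootstrap_paired_test(a, b, n_boot = 4000, seed = 4)
  r2 <- bootstrap_paired_test(a, b, n_boot = 4000, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- bootstrap_paired_test(b, a, n_boot = 4000, seed = 4)
  expect_equal(r1$p_value, r3$p_value, tolerance = 0.05)
  expect_warning(bootstrap_paired_test(a, b, n_boot = 50), "coarse")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(c(0.005, 0.4), 2), c(0.01, 0.8))
  expect_equal(bonferroni(0.7, 2), 1)
  expect_equal(bonferroni(c(0.2, 0.9), 1e6)[2], 1)
  expect_equal(bonferroni(0.37, 1), 0.37)
  expect_error(bonferroni(c(0.5), 0), "m must be")
  expect_error(bonferroni(1.2), "outside")
})
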