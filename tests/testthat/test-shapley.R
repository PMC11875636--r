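test_that("linear value functions give the closed-form attribution", {
  set.seed(1)
  C <- 3; T_ <- 4                               # 3 channels x 1 window
  trial <- matrix(rnorm(C * T_), C, T_)
  bg <- array(rnorm(5 * C * T_), c(5, C, T_))
  w <- rnorm(C * T_)
  vf <- function(xb) apply(xb, 1, function(m) sum(w * as.vector(m)))
  m <- shapley_attributions(NULL, trial, bg, windows = 1, mode = "exact",
                            value_fn = vf)
  bg_mean <- apply(bg, c(2, 3), mean)
  closed <- rowSums(matrix(w, C, T_) * (trial - bg_mean))
  expect_equal(unname(m$values[, 1]), closed, tolerance = 1e-9)
  # efficiency: attributions sum to f(trial) - mean f(background)
  expect_equal(sum(m$values),
               attr(m, "full_value") - attr(m, "base_value"),
               tolerance = 1e-9)
})

test_that("exact mode matches the permutation-enumeration oracle", {
  set.seed(2)
  C <- 2; T_ <- 4; nw <- 2                       # 4 super-features
  trial <- matrix(rnorm(C * T_), C, T_)
  bg <- array(rnorm(6 * C * T_), c(6, C, T_))
  vf <- function(xb) apply(xb, 1, function(m) tanh(sum(m)) + sum(m^2) / 10)
  m <- shapley_attributions(NULL, trial, bg, windows = nw, mode = "exact",
                            value_fn = vf)
  bg_mean <- apply(bg, c(2, 3), mean)
  starts <- c(1, 3); ends <- c(2, 4)
  value <- function(mask) {               # mask over (channel, window) pairs
    x <- bg_mean
    for (k in which(mask)) {
      ci <- ((k - 1) %% C) + 1; wi <- ((k - 1) %/% C) + 1
      x[ci, starts[wi]:ends[wi]] <- trial[ci, starts[wi]:ends[wi]]
    }
    vf(array(x, c(1, C, T_)))
  }
  expect_equal(as.vector(m$values), shap_oracle(value, 4), tolerance = 1e-9)
})

test_that("symmetric duplicated features receive equal attributions", {
  set.seed(3)
  C <- 4; T_ <- 2
  trial <- matrix(rnorm(C * T_), C, T_)
  trial[2, ] <- trial[1, ]
  bg <- array(rnorm(8 * C * T_), c(8, C, T_))
  bg[, 2, ] <- bg[, 1, ]
  vf <- function(xb) apply(xb, 1, function(m) {
    x <- matrix(m, C, T_)
    sin(sum(x[1, ]) + sum(x[2, ])) + sum(x[3, ] * x[4, ])
  })
  m <- shapley_attributions(NULL, trial, bg, windows = 1, mode = "exact",
                            value_fn = vf)
  expect_equal(m$values[1, 1], m$values[2, 1], tolerance = 1e-9)
})

test_that("sampled mode approximates exact values and stays efficient", {
  set.seed(4)
  C <- 4; T_ <- 4; nw <- 2                       # 8 super-features
  trial <- matrix(rnorm(C * T_), C, T_)
  bg <- array(rnorm(6 * C * T_), c(6, C, T_))
  vf <- function(xb) apply(xb, 1, function(m) tanh(sum(m) / 4) + sum(m^2) / 20)
  ex <- shapley_attributions(NULL, trial, bg, windows = nw, mode = "exact",
                             value_fn = vf)
  sa <- shapley_attributions(NULL, trial, bg, windows = nw, mode = "sampled",
                             n_permutations = 2000, seed = 7, value_fn = vf)
  rng <- diff(range(ex$values))
  expect_lt(max(abs(sa$values - ex$values)), 0.02 * rng)
  expect_equal(sum(sa$values),
               attr(sa, "full_value") - attr(sa, "base_value"),
               tolerance = 1e-9)
  # deterministic under a fixed seed
  sa2 <- shapley_attributions(NULL, trial, bg, windows = nw, mode = "sampled",
                              n_permutations = 50, seed = 7, value_fn = vf)
  sa3 <- shapley_attributions(NULL, trial, bg, windows = nw, mode = "sampled",
                              n_permutations = 50, seed = 7, value_fn = vf)
  expect_identical(sa2$values, sa3$values)
})

test_that("attribution scaling: absolute value first, then per-window min-max", {
  m <- attribution_map(c("a", "b", "c"), 0, matrix(c(-2, 0, 2), 3, 1))
  s <- scale_absolute(m)
  expect_equal(unname(s$values[, 1]), c(1, 0, 1))
  # constant window maps to the neutral 0.5
  m2 <- attribution_map(c("a", "b"), c(0, 1), matrix(c(3, 3, 1, 2), 2, 2))
  s2 <- scale_absolute(m2)
  expect_equal(unname(s2$values[, 1]), c(0.5, 0.5))
  expect_equal(unname(s2$values[, 2]), c(0, 1))
  # invariant to positive rescaling of the raw attributions
  m3 <- m; m3$values <- m$values * 17
  expect_equal(scale_absolute(m3)$values, s$values)
})

test_that("topography interpolation is bounded and peaks at the hot electrode", {
  mont <- make_default_montage()
  g <- topography_grid(rep(3, 64), mont, resolution = 32)
  expect_equal(range(g$grid, na.rm = TRUE), c(3, 3), tolerance = 1e-9)
  expect_true(all(is.na(g$grid[outer(g$x^2, g$y^2, `+`) > 1])))
  v <- numeric(64); v[match("AF8", mont$channel_names)] <- 1
  g2 <- topography_grid(v, mont, resolution = 64)
  peak <- which(g2$grid == max(g2$grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  target <- mont$positions["AF8", ]
  expect_lt(sqrt((g2$x[peak[1]] - target[1])^2 + (g2$y[peak[2]] - target[2])^2),
            0.08)
  expect_gte(min(g2$grid, na.rm = TRUE), 0)
  expect_lte(max(g2$grid, na.rm = TRUE), 1)
})

test_that("ROI extraction ranks channels and splits hemispheres", {
  mont <- make_default_montage()
  roi <- roi_channels(mont)
  vals <- matrix(0.1, 64, 2,
                 dimnames = list(mont$channel_names, NULL))
  vals[roi, ] <- matrix(seq(0.6, 1, length.out = 10), 10, 2)
  m <- attribution_map(mont$channel_names, c(0, 2), vals, scaled = TRUE)
  ex <- extract_rois(m, mont, top_k = 10)
  expect_setequal(ex$right, mont$rois$right_frontal)
  expect_setequal(ex$left, mont$rois$left_frontal)
  expect_length(ex$right, 5)
  all_ex <- extract_rois(m, mont, top_k = 64)
  expect_setequal(c(all_ex$right, all_ex$left), mont$channel_names)
  expect_error(extract_rois(m, mont, top_k = 65), "top_k")
  # deterministic tie-break by montage order among equal scores
  tied <- attribution_map(mont$channel_names, 0, matrix(0.5, 64, 1),
                          scaled = TRUE)
  ex2 <- extract_rois(tied, mont, top_k = 3)
  expect_setequal(c(ex2$right, ex2$left), mont$channel_names[1:3])
})
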