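toy_config <- function(bands = list(band_spec("d", 1, 4), band_spec("t", 4, 8)),
                       ...) {
  args <- utils::modifyList(
    list(bands = bands, n_channels = 5, n_samples = 24, input_rate = 32,
         temporal_filters = 3, temporal_kernel = 7, depth_multiplier = 2,
         pool_factor = 6, se_reduction = 2, dropout = 0, n_classes = 2),
    list(...))
  do.call(model_config, args)
}

branch_params <- function(cfg) {
  # analytic per-branch parameter count: temporal kernels + spatial filters
  cfg$temporal_filters * cfg$temporal_kernel +
    cfg$temporal_filters * cfg$depth_multiplier * cfg$n_channels +
    cfg$temporal_filters * cfg$depth_multiplier
}

test_that("architecture structure follows the configuration", {
  cfg <- toy_config(bands = default_bands())
  m <- build_model(cfg, seed = 1)
  # one kernel/spatial block per band
  expect_setequal(grep("^kern_", names(m$params), value = TRUE),
                  paste0("kern_", c("delta", "theta", "alpha")))
  # SE gate dimension = bands x temporal_filters x depth_multiplier
  expect_equal(nrow(m$params$se_W2), 3 * 3 * 2)
  expect_equal(length(m$params$se_b2), 18)
  # two-band variant drops exactly one branch's parameters
  cfg2 <- toy_config()
  m2 <- build_model(cfg2, seed = 1)
  full_extra <- count_parameters(m) - count_parameters(m2)
  ln_out_diff <- (3 - 2) * cfg$temporal_filters * cfg$depth_multiplier *
    (cfg$n_samples %/% cfg$pool_factor)
  se_diff <- (18 * 9 + 9 + 9 * 18 + 18) - (12 * 6 + 6 + 6 * 12 + 12)
  expect_equal(full_extra,
               branch_params(cfg) + se_diff +
                 ln_out_diff * (2 + cfg$n_classes))  # LN gamma+beta, out W rows
})

test_that("initialisation is reproducible from the seed", {
  cfg <- toy_config()
  expect_identical(build_model(cfg, seed = 5)$params,
                   build_model(cfg, seed = 5)$params)
  expect_false(identical(build_model(cfg, seed = 5)$params,
                         build_model(cfg, seed = 6)$params))
})

test_that("parameter counting is exact and monotone", {
  expect_equal(count_parameters(list(W = matrix(0, 2, 10), b = numeric(2))), 22)
  cfg <- toy_config()
  cfg2 <- toy_config(temporal_filters = 6)
  expect_gt(count_parameters(build_model(cfg2, 1)),
            count_parameters(build_model(cfg, 1)))
  # the default model honours the lightweight contract
  expect_lt(count_parameters(build_model(model_config(), 1)), 60000)
})

test_that("config invariants are enforced", {
  expect_error(toy_config(temporal_kernel = 25), "temporal_kernel")
  expect_error(toy_config(se_reduction = 13), "se_reduction")
  expect_error(toy_config(n_channels = 0), "counts")
})

test_that("squeeze-and-excitation gates are bounded, symmetric, and can pass through", {
  set.seed(2)
  x <- matrix(rnorm(4 * 10), 4, 10)
  out <- squeeze_excite(x, r = 2)
  g <- attr(out, "gates")
  expect_true(all(g > 0 & g < 1))
  expect_equal(out, x * g, ignore_attr = TRUE)
  # saturated excitation bias: gates ~ 1, output ~ input
  w <- list(W1 = matrix(0, 2, 4), b1 = numeric(2),
            W2 = matrix(0, 4, 2), b2 = rep(30, 4))
  out1 <- squeeze_excite(x, weights = w)
  expect_equal(out1, x, ignore_attr = TRUE, tolerance = 1e-9)
  # duplicated feature maps with symmetric weights get equal gates
  xs <- rbind(x, x[1, ])                       # row 5 duplicates row 1
  ws <- list(W1 = matrix(stats::rnorm(2 * 5), 2, 5), b1 = stats::rnorm(2),
             W2 = matrix(stats::rnorm(5 * 2), 5, 2), b2 = stats::rnorm(5))
  ws$W1[, 5] <- ws$W1[, 1]
  ws$W2[5, ] <- ws$W2[1, ]; ws$b2[5] <- ws$b2[1]
  g2 <- attr(squeeze_excite(xs, weights = ws), "gates")
  expect_equal(g2[5], g2[1])
})

test_that("analytic gradients match finite differences", {
  set.seed(1)
  cfg <- toy_config()
  model <- build_model(cfg, seed = 3)
  B <- 4
  xb <- lapply(1:2, function(i) array(rnorm(5 * 24 * B), c(5, 24, B)))
  y <- c(0L, 1L, 1L, 0L)
  fwd <- bandfocus:::.forward
  loss_fn <- function(params) {
    pr <- fwd(params, cfg, xb, train = FALSE)$probs
    -mean(log(pr[cbind(y + 1L, seq_len(B))]))
  }
  cache <- fwd(model$params, cfg, xb, train = FALSE)
  onehot <- matrix(0, 2, B); onehot[cbind(y + 1L, seq_len(B))] <- 1
  gr <- bandfocus:::.backward(model$params, cfg, xb, cache, onehot)
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(1e-8, abs(num) + abs(gr[[nm]][i])), 1e-5)
    }
  }
})

test_that("forward pass yields proper, permutation-equivariant probabilities", {
  set.seed(8)
  cfg <- toy_config()
  model <- build_model(cfg, seed = 2)
  stack <- structure(list(
    bands = cfg$bands,
    data = array(rnorm(2 * 6 * 5 * 24), c(2, 6, 5, 24)),
    labels = rep(0L, 6), channel_names = paste0("ch", 1:5),
    times = seq_len(24) / 32, sampling_rate = 32, subject_id = "x"),
    class = "bfn_bandstack")
  pr <- forward(model, stack)
  expect_equal(unname(rowSums(pr)), rep(1, 6), tolerance = 1e-6)
  expect_true(all(pr >= 0))
  # permuting trials permutes rows identically
  perm <- c(3, 1, 6, 2, 5, 4)
  stack2 <- stack
  stack2$data <- stack$data[, perm, , , drop = FALSE]
  expect_equal(forward(model, stack2), pr[perm, ], tolerance = 1e-12)
  # evaluation mode is bit-deterministic
  expect_identical(forward(model, stack), pr)
  # band mismatch is rejected
  stack3 <- stack
  stack3$bands <- list(band_spec("x", 2, 6), band_spec("t", 4, 8))
  expect_error(forward(model, stack3), "band mismatch")
})

test_that("checkpoints round-trip bit-exactly", {
  cfg <- toy_config()
  model <- build_model(cfg, seed = 4)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_identical(load_model(path)$params, model$params)
  unlink(path)
})
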