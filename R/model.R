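#' Architecture configuration for the band-branched classifier
#'
#' One branch per frequency band: a temporal convolution
#' (`temporal_filters` kernels of `temporal_kernel` samples, applied per
#' electrode), an electrode-aggregating depthwise spatial filter spanning
#' all channels (`depth_multiplier` spatial filters per temporal filter,
#' collapsing the electrode axis), an exponential-linear nonlinearity,
#' temporal average pooling and dropout. Branch feature maps are
#' concatenated, gated by a squeeze-and-excitation attention block
#' (bottleneck ratio `se_reduction`) so the network can re-weight bands per
#' trial, layer-normalised over the flattened feature axis, and classified
#' by an affine softmax layer.
#'
#' Because the temporal and spatial stages are both linear and the temporal
#' kernels use same-padding, the implementation applies the spatial filters
#' first and convolves the resulting virtual channels — mathematically
#' identical, roughly `n_channels / (temporal_filters * depth_multiplier)`
#' times cheaper.
#'
#' Branch inputs are fixed zero-phase band-pass copies of the signal
#' (see [band_decompose()]), decimated by `decimate` (valid because all
#' default bands lie well below the decimated Nyquist).
#'
#' @param bands list of [band_spec()] (default delta, theta, alpha).
#' @param n_channels,n_samples input geometry *after* decimation.
#' @param input_rate effective sampling rate of the model input in Hz.
#' @param temporal_filters kernels per branch (default 8).
#' @param temporal_kernel kernel length in samples (default 0.5 s at
#'   `input_rate`).
#' @param depth_multiplier spatial filters per temporal filter (default 2).
#' @param pool_factor average-pool width in samples (default 32).
#' @param se_reduction squeeze-and-excitation bottleneck ratio (default 4).
#' @param dropout dropout probability in each branch (default 0.25).
#' @param n_classes number of output classes (default 2).
#' @param decimate decimation factor applied to band-filtered input.
#' @return object of class `bfn_modelconfig`.
#' @export
model_config <- function(bands = default_bands(), n_channels = 64,
                         n_samples = 128, input_rate = 32,
                         temporal_filters = 8,
                         temporal_kernel = max(2L, round(0.5 * input_rate)),
                         depth_multiplier = 2, pool_factor = 32,
                         se_reduction = 4, dropout = 0.25, n_classes = 2,
                         decimate = 4) {
  counts <- c(n_channels, n_samples, temporal_filters, temporal_kernel,
              depth_multiplier, pool_factor, se_reduction, n_classes, decimate)
  if (any(counts < 1)) stop_config("all architecture counts must be >= 1")
  if (!length(bands)) stop_config("at least one band is required")
  if (temporal_kernel > n_samples)
    stop_config("temporal_kernel (%d) must be <= n_samples (%d)",
                temporal_kernel, n_samples)
  if (pool_factor > n_samples)
    stop_config("pool_factor must be <= n_samples")
  maps <- length(bands) * temporal_filters * depth_multiplier
  if (se_reduction > maps)
    stop_config("se_reduction (%d) exceeds total feature maps (%d)",
                se_reduction, maps)
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  structure(list(bands = bands, n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), input_rate = input_rate,
                 temporal_filters = as.integer(temporal_filters),
                 temporal_kernel = as.integer(temporal_kernel),
                 depth_multiplier = as.integer(depth_multiplier),
                 pool_factor = as.integer(pool_factor),
                 se_reduction = as.integer(se_reduction),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 decimate = as.integer(decimate)),
            class = "bfn_modelconfig")
}

.cfg_maps_per_band <- function(cfg) cfg$temporal_filters * cfg$depth_multiplier
.cfg_maps_total <- function(cfg) length(cfg$bands) * .cfg_maps_per_band(cfg)
.cfg_pooled_len <- function(cfg) cfg$n_samples %/% cfg$pool_factor
.cfg_feat_dim <- function(cfg) .cfg_maps_total(cfg) * .cfg_pooled_len(cfg)

.glorot <- function(nr, nc, fan_in, fan_out) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (fan_in + fan_out))), nr, nc)
}

#' Build an (untrained) band-branched model
#'
#' Initialises all trainable weights reproducibly from `seed` (Glorot-scaled
#' normals; gains and biases at their neutral values).
#'
#' @param config a [model_config()].
#' @param seed integer init seed.
#' @return object of class `bfn_model` with `$params`, `$config`,
#'   `$training_log` (empty), `$seed`. Preprocessing metadata is attached by
#'   [bfn_fit()].
#' @export
build_model <- function(config, seed = 1L) {
  if (!inherits(config, "bfn_modelconfig")) stop_config("config must be a bfn_modelconfig")
  K <- config$temporal_kernel; F1 <- config$temporal_filters
  M <- .cfg_maps_per_band(config); C <- config$n_channels
  Mt <- .cfg_maps_total(config); Fd <- .cfg_feat_dim(config)
  r <- max(1L, Mt %/% config$se_reduction)
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    for (b in vapply(config$bands, `[[`, "", "name")) {
      p[[paste0("kern_", b)]] <- .glorot(K, F1, K, K)
      p[[paste0("Wspat_", b)]] <- .glorot(M, C, C, M)
      p[[paste0("bspat_", b)]] <- numeric(M)
    }
    p$se_W1 <- .glorot(r, Mt, Mt, r); p$se_b1 <- numeric(r)
    p$se_W2 <- .glorot(Mt, r, r, Mt); p$se_b2 <- numeric(Mt)
    p$ln_gamma <- rep(1, Fd); p$ln_beta <- numeric(Fd)
    p$out_W <- .glorot(config$n_classes, Fd, Fd, config$n_classes)
    p$out_b <- numeric(config$n_classes)
    p
  })
  structure(list(config = config, params = params, preproc = NULL,
                 training_log = data.frame(), seed = as.integer(seed)),
            class = "bfn_model")
}

#' Count trainable parameters
#'
#' @param model a `bfn_model`, or any (nested) list of numeric arrays.
#' @return total number of trainable scalars.
#' @examples
#' count_parameters(list(W = matrix(0, 2, 10), b = numeric(2)))  # 22
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "bfn_model")) model$params else model
  cnt <- function(x) {
    if (is.list(x)) sum(vapply(x, cnt, numeric(1)))
    else if (is.numeric(x)) length(x)
    else 0
  }
  cnt(p)
}

.elu <- function(x) pmax(x, 0) + exp(pmin(x, 0)) - 1
.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Squeeze-and-excitation channel attention
#'
#' Squeeze: each feature map (row) is mean-pooled over time to a scalar.
#' Excitation: the scalars pass through a two-layer bottleneck
#' (`maps -> ceiling(maps / r) -> maps`) with a rectifier in the middle and
#' a logistic squashing at the end, yielding one gate in (0, 1) per map.
#' The output is the input with each row rescaled by its gate.
#'
#' @param features `maps x time` numeric matrix.
#' @param r bottleneck reduction ratio (bottleneck width is
#'   `max(1, floor(maps / r))`).
#' @param weights optional `list(W1, b1, W2, b2)`; random Glorot init from
#'   `seed` when omitted.
#' @param seed init seed used when `weights` is `NULL`.
#' @return matrix of the same shape; `attr(, "gates")` carries the per-map
#'   gates.
#' @export
squeeze_excite <- function(features, r = 4, weights = NULL, seed = 1L) {
  features <- as.matrix(features)
  m <- nrow(features)
  rd <- max(1L, m %/% as.integer(r))
  if (is.null(weights)) {
    weights <- with_seed(derive_seed(seed, "se"), list(
      W1 = .glorot(rd, m, m, rd), b1 = numeric(rd),
      W2 = .glorot(m, rd, rd, m), b2 = numeric(m)))
  }
  z <- rowMeans(features)
  h <- pmax(weights$W1 %*% z + weights$b1, 0)
  g <- drop(.sigmoid(weights$W2 %*% h + weights$b2))
  out <- features * g
  attr(out, "gates") <- g
  out
}

# ---------------------------------------------------------------------------
# Forward / backward engine. Inputs are per-band arrays C x T x B. The
# temporal convolution runs in the frequency domain; with same-padding the
# output at t is sum_k h[k] * s[t + k0 - k + 1], k0 = floor(K/2).

.conv_fft <- function(st, kern, kcol) {
  # st: T x n matrix of signals; kern: K x F1; kcol: kernel index per column
  T_ <- nrow(st); K <- nrow(kern)
  Lf <- stats::nextn(T_ + K, c(2, 3, 5))
  FS <- stats::mvfft(rbind(st, matrix(0, Lf - T_, ncol(st))))
  KF <- stats::mvfft(rbind(kern, matrix(0, Lf - K, ncol(kern))))
  cf <- Re(stats::mvfft(FS * KF[, kcol, drop = FALSE], inverse = TRUE)) / Lf
  k0 <- K %/% 2
  list(y = cf[k0 + seq_len(T_), , drop = FALSE], FS = FS, KF = KF, Lf = Lf)
}

.conv_fft_backward <- function(dy, st, kern, kcol, kgroups, FS, Lf) {
  T_ <- nrow(st); K <- nrow(kern); k0 <- K %/% 2
  DY <- stats::mvfft(rbind(dy, matrix(0, Lf - T_, ncol(dy))))
  # grad wrt input: correlation with the kernel
  KFr <- stats::mvfft(rbind(kern[K:1, , drop = FALSE], matrix(0, Lf - K, ncol(kern))))
  dsf <- Re(stats::mvfft(DY * KFr[, kcol, drop = FALSE], inverse = TRUE)) / Lf
  ds <- dsf[(K - k0 - 1) + seq_len(T_), , drop = FALSE]
  # grad wrt kernels: cross-correlation sum_t dy[t] s[t + k0 - k + 1]
  P <- FS * Conj(DY)
  dk <- matrix(0, K, ncol(kern))
  m <- k0 - seq_len(K) + 1
  ridx <- (m %% Lf) + 1
  for (f in seq_len(ncol(kern))) {
    cols <- kgroups[[f]]
    if (!length(cols)) next
    pf <- if (length(cols) == 1) P[, cols] else rowSums(P[, cols, drop = FALSE])
    rc <- Re(stats::fft(pf, inverse = TRUE)) / Lf
    dk[, f] <- rc[ridx]
  }
  list(ds = ds, dk = dk)
}

# Full forward pass; when `train` is TRUE dropout masks are drawn from the
# current RNG stream and kept in the cache for the backward pass.
.forward <- function(params, cfg, xb, train = FALSE) {
  bn <- vapply(cfg$bands, `[[`, "", "name")
  M <- .cfg_maps_per_band(cfg); Tp <- .cfg_pooled_len(cfg)
  P <- cfg$pool_factor; T_ <- cfg$n_samples
  B <- dim(xb[[1]])[3]
  Mt <- .cfg_maps_total(cfg)
  U <- array(0, c(Mt, Tp, B))
  cache <- list(bands = list(), B = B)
  kcol <- rep(rep(seq_len(cfg$temporal_filters), each = cfg$depth_multiplier), B)
  kgroups <- split(seq_along(kcol), kcol)
  for (i in seq_along(bn)) {
    b <- bn[i]
    Xm <- matrix(xb[[i]], cfg$n_channels, T_ * B)
    S <- params[[paste0("Wspat_", b)]] %*% Xm + params[[paste0("bspat_", b)]]
    st <- matrix(aperm(array(S, c(M, T_, B)), c(2, 1, 3)), T_, M * B)
    cv <- .conv_fft(st, params[[paste0("kern_", b)]], kcol)
    E <- exp(pmin(cv$y, 0))                   # ELU derivative; ELU = max+E-1
    A <- pmax(cv$y, 0) + E - 1
    Tt <- Tp * P
    Q <- matrix(colMeans(array(A[seq_len(Tt), , drop = FALSE], c(P, Tp, M * B))),
                Tp, M * B)
    drop_mask <- NULL
    if (train && cfg$dropout > 0) {
      drop_mask <- matrix(stats::runif(Tp * M * B) >= cfg$dropout, Tp, M * B) /
        (1 - cfg$dropout)
      Q <- Q * drop_mask
    }
    U[(i - 1) * M + seq_len(M), , ] <- aperm(array(Q, c(Tp, M, B)), c(2, 1, 3))
    cache$bands[[b]] <- list(Xm = Xm, st = st, dE = E, FS = cv$FS,
                             Lf = cv$Lf, drop_mask = drop_mask)
  }
  cache$kgroups <- kgroups
  # squeeze-and-excitation over the concatenated maps
  Um <- matrix(U, Mt, Tp * B)                        # columns tp-fast per trial
  pool <- matrix(0, Tp * B, B)
  pool[cbind(seq_len(Tp * B), rep(seq_len(B), each = Tp))] <- 1 / Tp
  z <- Um %*% pool                                   # Mt x B
  h <- pmax(params$se_W1 %*% z + params$se_b1, 0)
  g <- .sigmoid(params$se_W2 %*% h + params$se_b2)   # Mt x B
  V <- array(Um * g[, rep(seq_len(B), each = Tp)], c(Mt, Tp, B))
  # layer norm over the flattened feature axis, per trial
  Vm <- matrix(V, Mt * Tp, B)
  mu <- colMeans(Vm)
  cen <- sweep(Vm, 2, mu)
  va <- colMeans(cen^2)
  inv <- 1 / sqrt(va + 1e-5)
  xhat <- sweep(cen, 2, inv, `*`)
  ln <- xhat * params$ln_gamma + params$ln_beta
  logits <- params$out_W %*% ln + params$out_b
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), `/`)
  cache <- c(cache, list(U = U, pool = pool, z = z, h = h, g = g,
                         xhat = xhat, inv = inv, ln = ln, probs = probs,
                         kcol = kcol))
  cache
}

.backward <- function(params, cfg, xb, cache, y_onehot) {
  bn <- vapply(cfg$bands, `[[`, "", "name")
  M <- .cfg_maps_per_band(cfg); Tp <- .cfg_pooled_len(cfg)
  P <- cfg$pool_factor; T_ <- cfg$n_samples; B <- cache$B
  Mt <- .cfg_maps_total(cfg); Fd <- Mt * Tp
  gr <- list()
  dlogits <- (cache$probs - y_onehot) / B
  gr$out_W <- tcrossprod(dlogits, cache$ln)
  gr$out_b <- rowSums(dlogits)
  dln <- crossprod(params$out_W, dlogits)
  gr$ln_gamma <- rowSums(dln * cache$xhat)
  gr$ln_beta <- rowSums(dln)
  dxh <- dln * params$ln_gamma
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * cache$xhat)
  dVm <- sweep(sweep(dxh, 2, m1) - sweep(cache$xhat, 2, m2, `*`),
               2, cache$inv, `*`)
  dim(dVm) <- c(Mt, Tp * B)
  bexp <- rep(seq_len(B), each = Tp)
  Um <- matrix(cache$U, Mt, Tp * B)
  dUm <- dVm * cache$g[, bexp]
  dg <- (dVm * Um) %*% (cache$pool * Tp)             # Mt x B
  dpre2 <- dg * cache$g * (1 - cache$g)
  gr$se_W2 <- tcrossprod(dpre2, cache$h)
  gr$se_b2 <- rowSums(dpre2)
  dh <- crossprod(params$se_W2, dpre2)
  dpre1 <- dh * (cache$h > 0)
  gr$se_W1 <- tcrossprod(dpre1, cache$z)
  gr$se_b1 <- rowSums(dpre1)
  dz <- crossprod(params$se_W1, dpre1)
  dUm <- dUm + (dz / Tp)[, bexp]
  dU <- array(dUm, c(Mt, Tp, B))
  for (i in seq_along(bn)) {
    b <- bn[i]
    cb <- cache$bands[[b]]
    dQ <- matrix(aperm(dU[(i - 1) * M + seq_len(M), , , drop = FALSE],
                       c(2, 1, 3)), Tp, M * B)
    if (!is.null(cb$drop_mask)) dQ <- dQ * cb$drop_mask
    Tt <- Tp * P
    dA <- matrix(0, T_, M * B)
    dA[seq_len(Tt), ] <- dQ[rep(seq_len(Tp), each = P), , drop = FALSE] / P
    dy <- dA * cb$dE
    kern <- params[[paste0("kern_", b)]]
    cvb <- .conv_fft_backward(dy, cb$st, kern, cache$kcol, cache$kgroups,
                              cb$FS, cb$Lf)
    gr[[paste0("kern_", b)]] <- cvb$dk
    dS <- matrix(aperm(array(cvb$ds, c(T_, M, B)), c(2, 1, 3)), M, T_ * B)
    gr[[paste0("Wspat_", b)]] <- tcrossprod(dS, cb$Xm)
    gr[[paste0("bspat_", b)]] <- rowSums(dS)
  }
  gr
}

# Evaluation-mode class probabilities for per-band input arrays (C x T x B).
.predict_stacks <- function(params, cfg, xb) {
  t(.forward(params, cfg, xb, train = FALSE)$probs)
}

#' Forward pass: class probabilities for a band stack
#'
#' Evaluation-mode (deterministic, dropout off) forward pass through a
#' model. The stack must already be standardized and decimated exactly as
#' during training; [predict.bfn_model()] is the convenience wrapper that
#' applies a fitted model's stored preprocessing to raw epochs.
#'
#' @param model a `bfn_model`.
#' @param stack a `bfn_bandstack` whose bands match `model$config$bands` and
#'   whose geometry matches the model input.
#' @return `trials x n_classes` matrix of probabilities (rows sum to 1).
#' @export
forward <- function(model, stack) {
  cfg <- model$config
  got <- vapply(stack$bands, `[[`, "", "name")
  want <- vapply(cfg$bands, `[[`, "", "name")
  if (!identical(got, want))
    stop_config("band mismatch: stack (%s) vs model (%s)",
                paste(got, collapse = ","), paste(want, collapse = ","))
  d <- dim(stack$data)
  if (d[3] != cfg$n_channels || d[4] != cfg$n_samples)
    stop_config("stack geometry %dx%d does not match model input %dx%d",
                d[3], d[4], cfg$n_channels, cfg$n_samples)
  xb <- lapply(seq_len(d[1]), function(i)
    aperm(array(stack$data[i, , , , drop = FALSE], d[2:4]), c(2, 3, 1)))
  pr <- .predict_stacks(model$params, cfg, xb)
  colnames(pr) <- paste0("class", seq_len(cfg$n_classes) - 1)
  pr
}

#' Save / load a fitted model
#'
#' The checkpoint holds the configuration, all weight arrays, the stored
#' preprocessing transform and the training log; a round trip is bit-exact.
#'
#' @param model a `bfn_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "bfn_model")) stop_config("not a bfn_model checkpoint")
  m
}

#' @export
print.bfn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<bfn_model> %d-band classifier (%s), %d channels x %d samples\n",
              length(cfg$bands),
              paste(vapply(cfg$bands, `[[`, "", "name"), collapse = "/"),
              cfg$n_channels, cfg$n_samples))
  cat(sprintf("  %d trainable parameters; %s\n", count_parameters(x),
              if (nrow(x$training_log)) sprintf("trained %d epochs",
                                                max(x$training_log$epoch))
              else "untrained"))
  invisible(x)
}

#' @export
coef.bfn_model <- function(object, ...) object$params
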