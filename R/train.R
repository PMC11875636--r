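#' Training configuration
#'
#' Adaptive-moment (Adam) optimisation of the cross-entropy loss with early
#' stopping on a validation split drawn from the training subjects' trials
#' (stratified by subject and label), so model selection never touches a
#' held-out test subject.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param validation_fraction fraction of training trials used for
#'   validation (must be in (0, 0.5)).
#' @param seed seed for weight init, shuffling, dropout and the validation
#'   split (per-stage streams are derived from it).
#' @return object of class `bfn_trainconfig`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 15, early_stop_patience = 4,
                         validation_fraction = 0.2, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop_config("validation_fraction must be in (0, 0.5)")
  if (learning_rate <= 0 || batch_size < 1 || max_epochs < 1 ||
      early_stop_patience < 1)
    stop_config("training counts must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "bfn_trainconfig")
}

.adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.ce_loss <- function(probs, y) {
  # probs: classes x B; y: integer labels 0-based
  -mean(log(pmax(probs[cbind(y + 1L, seq_along(y))], 1e-12)))
}

.eval_loss_acc <- function(params, cfg, xb, y, chunk = 512L) {
  n <- length(y)
  tot <- 0; correct <- 0
  for (s in seq(1L, n, by = chunk)) {
    ix <- s:min(s + chunk - 1L, n)
    xs <- lapply(xb, function(a) a[, , ix, drop = FALSE])
    pr <- .forward(params, cfg, xs, train = FALSE)$probs
    tot <- tot + .ce_loss(pr, y[ix]) * length(ix)
    correct <- correct + sum(max.col(t(pr), ties.method = "first") - 1L == y[ix])
  }
  c(loss = tot / n, acc = 100 * correct / n)
}

# Stratified validation indices: `frac` of each (subject, label) cell.
.val_split <- function(subjects, labels, frac, seed) {
  with_seed(seed, {
    idx <- integer(0)
    for (cell in split(seq_along(labels), list(subjects, labels), drop = TRUE)) {
      k <- max(1L, round(frac * length(cell)))
      idx <- c(idx, sample(cell, k))
    }
    sort(idx)
  })
}

# Core trainer: assembles standardized train/validation tensors directly
# from the per-subject stacks (no full-cohort intermediate copy) and runs
# the Adam loop.
.train_engine <- function(config, tc, stacks, stats, seed) {
  meta <- .collect_meta(stacks)
  y <- meta$labels; subjects <- meta$subjects
  n <- length(y)
  val <- .val_split(subjects, y, tc$validation_fraction,
                    derive_seed(seed, "valsplit"))
  tr <- setdiff(seq_len(n), val)
  xtr <- .assemble_subset(stacks, stats, tr)
  xval <- .assemble_subset(stacks, stats, val)
  ytr <- y[tr]; yval <- y[val]
  model <- build_model(config, seed = derive_seed(seed, "init-outer"))
  params <- model$params
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  best <- list(params = params, loss = Inf, epoch = 0L)
  wait <- 0L; step <- 0L
  log <- vector("list", tc$max_epochs)
  with_seed(derive_seed(seed, "train-loop"), {
    for (ep in seq_len(tc$max_epochs)) {
      ord <- sample(length(ytr))
      ep_loss <- 0
      for (s in seq(1L, length(ord), by = tc$batch_size)) {
        ix <- ord[s:min(s + tc$batch_size - 1L, length(ord))]
        xs <- lapply(xtr, function(a) a[, , ix, drop = FALSE])
        cache <- .forward(params, config, xs, train = TRUE)
        yb <- ytr[ix]
        ep_loss <- ep_loss + .ce_loss(cache$probs, yb) * length(ix)
        onehot <- matrix(0, config$n_classes, length(ix))
        onehot[cbind(yb + 1L, seq_along(ix))] <- 1
        gr <- .backward(params, config, xs, cache, onehot)
        step <- step + 1L
        upd <- .adam_step(params, gr, state, tc$learning_rate, step)
        params <- upd$params; state <- upd$state
      }
      ep_loss <- ep_loss / length(ytr)
      if (!is.finite(ep_loss))
        stop("training diverged: non-finite loss at epoch ", ep)
      ev <- .eval_loss_acc(params, config, xval, yval)
      log[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss,
                              val_loss = ev[["loss"]], val_acc = ev[["acc"]])
      if (ev[["loss"]] < best$loss - 1e-5) {
        best <- list(params = params, loss = ev[["loss"]], epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$early_stop_patience) break
      }
    }
  })
  model$params <- best$params
  model$training_log <- do.call(rbind, log[!vapply(log, is.null, TRUE)])
  model$seed <- as.integer(seed)
  model
}

# Pool standardization statistics over a list of per-subject band stacks.
.pooled_stats <- function(stacks) {
  d <- dim(stacks[[1]]$data)
  n <- 0; s1 <- matrix(0, d[1], d[3]); s2 <- matrix(0, d[1], d[3])
  for (st in stacks) {
    dd <- dim(st$data)
    n <- n + dd[2] * dd[4]
    for (i in seq_len(d[1])) {
      m <- matrix(st$data[i, , , ], dd[2], dd[3] * dd[4])   # trials x (C*T)
      s1[i, ] <- s1[i, ] + rowSums(matrix(colSums(m), dd[3], dd[4]))
      s2[i, ] <- s2[i, ] + rowSums(matrix(colSums(m^2), dd[3], dd[4]))
    }
  }
  center <- s1 / n
  sc <- sqrt(pmax(s2 / n - center^2, 0) * n / (n - 1))
  if (any(sc == 0)) {
    warning("zero-variance (band, channel) pairs: scale set to 1")
    sc[sc == 0] <- 1
  }
  list(center = center, scale = sc)
}

# Trial metadata across a list of stacks, in concatenation order.
.collect_meta <- function(stacks) {
  list(labels = unlist(lapply(stacks, `[[`, "labels")),
       subjects = rep(vapply(stacks, `[[`, "", "subject_id"),
                      vapply(stacks, function(s) dim(s$data)[2], integer(1))))
}

# Standardized per-band C x T x n tensors for a subset of global trial
# indices (in the stacks' concatenation order).
.assemble_subset <- function(stacks, stats, sel) {
  d <- dim(stacks[[1]]$data)
  ns <- vapply(stacks, function(s) dim(s$data)[2], integer(1))
  offs <- cumsum(c(0L, ns))
  xb <- lapply(seq_len(d[1]), function(i) array(0, c(d[3], d[4], length(sel))))
  at <- 0L
  for (k in seq_along(stacks)) {
    loc <- sel[sel > offs[k] & sel <= offs[k + 1]] - offs[k]
    if (!length(loc)) next
    cen <- stats$center; scl <- stats$scale
    for (i in seq_len(d[1])) {
      sub <- stacks[[k]]$data[i, loc, , , drop = FALSE]   # 1 x n x C x T
      sub <- aperm(array(sub, c(length(loc), d[3], d[4])), c(2, 3, 1))
      xb[[i]][, , at + seq_along(loc)] <- (sub - cen[i, ]) / scl[i, ]
    }
    at <- at + length(loc)
  }
  xb
}

# Crop to the MI window, decompose into bands and decimate: the shared
# raw-epochs -> model-input transform. Bands are filtered and decimated one
# at a time so only one full-rate copy is ever alive.
.prep_stack <- function(epochs, bands, decimate, channels = NULL) {
  ep <- crop_epochs(epochs, channels = channels, window = c(0, Inf))
  d <- dim(ep$data)
  keep <- seq(1, d[3], by = decimate)
  data <- array(0, c(length(bands), d[1], d[2], length(keep)))
  for (i in seq_along(bands)) {
    hi <- bands[[i]]$high
    if (ep$sampling_rate / decimate < 2 * hi)
      stop_config("decimation would alias band content (edge %g Hz)", hi)
    data[i, , , ] <- bandpass_filter(ep$data, ep$sampling_rate,
                                     bands[[i]])[, , keep, drop = FALSE]
  }
  structure(list(bands = bands, data = data, labels = ep$labels,
                 channel_names = ep$channel_names, times = ep$times[keep],
                 sampling_rate = ep$sampling_rate / decimate,
                 subject_id = ep$subject_id),
            class = "bfn_bandstack")
}

#' Fit the band-branched classifier
#'
#' The single fitting entry point: takes raw labelled epochs (one subject or
#' a multi-subject list), applies the full preprocessing chain (MI-window
#' crop, zero-phase band decomposition, decimation, per-(band, channel)
#' standardisation with statistics from these training data only), and
#' trains the network with Adam and early stopping. The fitted object
#' stores the preprocessing transform so [predict.bfn_model()] can be
#' applied directly to raw epochs of unseen subjects.
#'
#' @param data a [epochs_set()] or list of them (the training subjects).
#' @param config a [model_config()]; `NULL` builds the default architecture
#'   for the data geometry.
#' @param tc a [train_config()].
#' @param channels optional channel subset (e.g. the 10 frontal ROI
#'   channels) to train on.
#' @return a fitted `bfn_model`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_subjects = 2, trials_per_condition = 10, seed = 7)
#' fit <- bfn_fit(generate_cohort(cfg), tc = train_config(max_epochs = 2))
#' predict(fit, generate_subject(cfg, 1))[1:2, ]
#' }
#' @export
bfn_fit <- function(data, config = NULL, tc = train_config(),
                    channels = NULL) {
  if (inherits(data, "bfn_epochs")) data <- list(data)
  bands <- if (is.null(config)) default_bands() else config$bands
  # default: decimate towards a 32 Hz effective model rate
  decim <- if (is.null(config))
    max(1L, as.integer(data[[1]]$sampling_rate %/% 32)) else config$decimate
  stacks <- lapply(data, .prep_stack, bands = bands, decimate = decim,
                   channels = channels)
  d <- dim(stacks[[1]]$data)
  if (is.null(config))
    config <- model_config(bands = bands, n_channels = d[3], n_samples = d[4],
                           input_rate = stacks[[1]]$sampling_rate,
                           decimate = decim)
  stats <- .pooled_stats(stacks)
  model <- .train_engine(config, tc, stacks, stats, tc$seed)
  model$preproc <- list(
    bands = bands, decimate = decim, stats = stats,
    channel_names = stacks[[1]]$channel_names,
    sampling_rate = data[[1]]$sampling_rate,
    window = c(0, Inf),
    train_subjects = vapply(data, `[[`, "", "subject_id"))
  model
}

#' Predict class probabilities for raw epochs
#'
#' Applies the preprocessing transform stored in the fitted model
#' (channel selection, MI-window crop, band decomposition, decimation,
#' train-statistics standardisation) and runs the evaluation-mode forward
#' pass.
#'
#' @param object a fitted `bfn_model` (from [bfn_fit()] or [run_loso()]).
#' @param newdata a [epochs_set()], or a numeric array
#'   `trials x channels x samples` (or single-trial `channels x samples`
#'   matrix) already restricted to the model's channels and MI window at the
#'   original sampling rate.
#' @param type `"prob"` for a `trials x classes` probability matrix,
#'   `"class"` for hard 0/1 labels (ties resolve to class 0).
#' @param ... unused.
#' @return probabilities or labels.
#' @export
predict.bfn_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  pp <- object$preproc
  if (is.null(pp)) stop_config("model has no stored preprocessing; use forward()")
  if (inherits(newdata, "bfn_epochs")) {
    ep <- crop_epochs(newdata, channels = pp$channel_names, window = pp$window)
    arr <- ep$data
    fs <- newdata$sampling_rate
  } else {
    arr <- newdata
    if (length(dim(arr)) == 2) arr <- array(arr, c(1L, dim(arr)))
    fs <- pp$sampling_rate
  }
  if (dim(arr)[2] != length(pp$channel_names))
    stop_config("expected %d channels, got %d", length(pp$channel_names),
                dim(arr)[2])
  stack <- structure(list(
    bands = pp$bands,
    data = {
      d <- dim(arr)
      a <- array(0, c(length(pp$bands), d))
      for (i in seq_along(pp$bands))
        a[i, , , ] <- bandpass_filter(arr, fs, pp$bands[[i]])
      a
    },
    labels = rep(0L, dim(arr)[1]), channel_names = pp$channel_names,
    times = seq_len(dim(arr)[3]) / fs, sampling_rate = fs,
    subject_id = "new"), class = "bfn_bandstack")
  stack <- decimate_stack(stack, pp$decimate)
  stack <- standardize_stack(stack, stats = pp$stats)
  pr <- forward(object, stack)
  if (type == "prob") pr else max.col(pr, ties.method = "first") - 1L
}

#' @export
summary.bfn_model <- function(object, ...) {
  print(object)
  if (nrow(object$training_log)) {
    tl <- object$training_log
    cat(sprintf("  best val loss %.4f (epoch %d), final val acc %.1f%%\n",
                min(tl$val_loss), which.min(tl$val_loss),
                tl$val_acc[nrow(tl)]))
  }
  invisible(object)
}
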