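#' Channel-by-time-window attribution map
#'
#' @param channel_names ordered channel labels.
#' @param window_starts window start times (seconds).
#' @param values `channels x windows` matrix of attribution values.
#' @param scaled whether values are absolute min-max scaled to [0, 1].
#' @param reference_description provenance of the background set.
#' @return object of class `bfn_attribution`.
#' @export
attribution_map <- function(channel_names, window_starts, values,
                            scaled = FALSE, reference_description = "") {
  values <- as.matrix(values)
  if (nrow(values) != length(channel_names) ||
      ncol(values) != length(window_starts))
    stop_config("values must be channels x windows")
  if (scaled && (min(values) < -1e-9 || max(values) > 1 + 1e-9))
    stop_config("scaled attribution values must lie in [0, 1]")
  structure(list(channel_names = as.character(channel_names),
                 window_starts = as.numeric(window_starts),
                 values = values, scaled = scaled,
                 reference_description = reference_description),
            class = "bfn_attribution")
}

#' @export
print.bfn_attribution <- function(x, ...) {
  cat(sprintf("<bfn_attribution> %d channels x %d windows (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled) "scaled [0,1]" else "signed"))
  invisible(x)
}

# Shapley weight for a coalition of size s among d players.
.shap_weight <- function(s, d) {
  exp(lfactorial(s) + lfactorial(d - s - 1) - lfactorial(d))
}

#' Shapley-value attributions over channel x time-window super-features
#'
#' Each super-feature is one channel over one time window. A feature absent
#' from a coalition is replaced by the background average (the per-sample
#' mean over the background trials), and the coalition value is the model
#' probability of the trial's predicted class. `mode = "exact"` enumerates
#' all coalitions (feasible up to ~20 features); `mode = "sampled"` uses
#' permutation sampling with `n_permutations` random feature orders, whose
#' telescoping marginal contributions keep the efficiency axiom exact.
#'
#' @param model a fitted `bfn_model` (with stored preprocessing), or any
#'   object accepted by `value_fn`.
#' @param trial `channels x samples` matrix: one trial over the model's
#'   channels and MI window at the original sampling rate.
#' @param background `trials x channels x samples` array of reference
#'   trials (class-balanced training trials are the usual choice).
#' @param windows number of equal time windows the epoch is partitioned
#'   into, or a vector of window start indices (samples).
#' @param mode `"exact"` or `"sampled"`.
#' @param n_permutations permutation draws in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param value_fn optional value function `function(x_batch)` returning a
#'   numeric value per trial of a `trials x channels x samples` batch; the
#'   default runs `predict(model, .)` and reads the predicted-class
#'   probability.
#' @param batch_size coalition inputs evaluated per model call.
#' @return an unscaled, signed [attribution_map()]; attribute
#'   `"base_value"` holds the mean background prediction and `"full_value"`
#'   the prediction on the intact trial, with
#'   `sum(values) = full_value - base_value` (efficiency).
#' @export
shapley_attributions <- function(model, trial, background, windows = 4,
                                 mode = c("sampled", "exact"),
                                 n_permutations = 64, seed = 1L,
                                 value_fn = NULL, batch_size = 256L) {
  mode <- match.arg(mode)
  trial <- as.matrix(trial)
  C <- nrow(trial); T_ <- ncol(trial)
  if (length(dim(background)) != 3 || dim(background)[2] != C ||
      dim(background)[3] != T_)
    stop_config("background must be trials x %d x %d", C, T_)
  if (dim(background)[1] < 1) stop_config("background set must be non-empty")
  if (length(windows) == 1) {
    nw <- as.integer(windows)
    starts <- floor(seq(0, T_, length.out = nw + 1))[seq_len(nw)] + 1L
  } else {
    starts <- as.integer(windows); nw <- length(starts)
  }
  ends <- c(starts[-1] - 1L, T_)
  d <- C * nw
  if (mode == "exact" && d > 20)
    stop_config("exact mode supports at most 20 super-features (got %d)", d)
  bg_mean <- apply(background, c(2, 3), mean)

  if (is.null(value_fn)) {
    pr_full <- predict(model, trial)
    cls <- which.max(pr_full[1, ])
    value_fn <- function(xb) predict(model, xb)[, cls]
  }
  # feature k (1-based) = channel ci + (wi - 1) * C
  compose <- function(masks) {
    # masks: n x d logical; returns n x C x T_ array of coalition inputs
    n <- nrow(masks)
    out <- array(rep(bg_mean, each = n), c(n, C, T_))
    for (k in seq_len(d)) {
      on <- masks[, k]
      if (!any(on)) next
      ci <- ((k - 1) %% C) + 1L
      wi <- ((k - 1) %/% C) + 1L
      sl <- starts[wi]:ends[wi]
      out[on, ci, sl] <- matrix(trial[ci, sl], sum(on), length(sl),
                                byrow = TRUE)
    }
    out
  }
  eval_masks <- function(masks) {
    n <- nrow(masks)
    vals <- numeric(n)
    for (s in seq(1L, n, by = batch_size)) {
      ix <- s:min(s + batch_size - 1L, n)
      vals[ix] <- value_fn(compose(masks[ix, , drop = FALSE]))
    }
    vals
  }

  if (mode == "exact") {
    nsub <- 2L^d
    masks <- matrix(FALSE, nsub, d)
    for (k in seq_len(d))
      masks[, k] <- bitwAnd(seq_len(nsub) - 1L, bitwShiftL(1L, k - 1L)) > 0
    v <- eval_masks(masks)
    sizes <- rowSums(masks)
    phi <- numeric(d)
    for (k in seq_len(d)) {
      without <- which(!masks[, k])
      with_ <- without + bitwShiftL(1L, k - 1L)
      w <- .shap_weight(sizes[without], d)
      phi[k] <- sum(w * (v[with_] - v[without]))
    }
    base <- v[1]; full <- v[nsub]
  } else {
    phi <- numeric(d)
    # antithetic pairs (each random order followed by its reverse) cancel
    # the leading Monte-Carlo error of the telescoping marginals
    perms <- with_seed(derive_seed(seed, "shap"), {
      half <- replicate(ceiling(n_permutations / 2), sample(d),
                        simplify = FALSE)
      out <- vector("list", 2 * length(half))
      out[seq(1, length(out), by = 2)] <- half
      out[seq(2, length(out), by = 2)] <- lapply(half, rev)
      out[seq_len(n_permutations)]
    })
    # evaluate each permutation's d+1 nested coalitions in batched calls
    masks <- matrix(FALSE, (d + 1L) * n_permutations, d)
    row <- 0L
    for (p in perms) {
      cur <- rep(FALSE, d)
      row <- row + 1L; masks[row, ] <- cur
      for (k in p) {
        cur[k] <- TRUE
        row <- row + 1L; masks[row, ] <- cur
      }
    }
    v <- eval_masks(masks)
    row <- 0L
    for (p in perms) {
      for (j in seq_len(d)) {
        phi[p[j]] <- phi[p[j]] + (v[row + j + 1L] - v[row + j])
      }
      row <- row + d + 1L
    }
    phi <- phi / n_permutations
    base <- v[1]; full <- v[d + 1L]
  }
  out <- attribution_map(rownames(trial) %||% paste0("ch", seq_len(C)),
                         (starts - 1L), matrix(phi, C, nw),
                         scaled = FALSE,
                         reference_description = sprintf(
                           "mean over %d background trials", dim(background)[1]))
  attr(out, "base_value") <- base
  attr(out, "full_value") <- full
  out
}

#' Absolute scaled aggregation of attribution maps
#'
#' Takes absolute values, averages across trials (maps), then min-max
#' scales to [0, 1] across channels within each time window — so within a
#' window the most influential channel reads 1 and the least 0. A window
#' with zero range maps to the neutral value 0.5.
#'
#' @param maps a single [attribution_map()] or list of them (same shape).
#' @return a scaled [attribution_map()].
#' @export
scale_absolute <- function(maps) {
  if (inherits(maps, "bfn_attribution")) maps <- list(maps)
  vals <- Reduce(`+`, lapply(maps, function(m) abs(m$values))) / length(maps)
  for (w in seq_len(ncol(vals))) {
    rng <- range(vals[, w])
    if (diff(rng) == 0) {
      vals[, w] <- 0.5
      bfn_log("WARN", "attribution window %d has zero range; set to 0.5", w)
    } else {
      vals[, w] <- (vals[, w] - rng[1]) / diff(rng)
    }
  }
  attribution_map(maps[[1]]$channel_names, maps[[1]]$window_starts, vals,
                  scaled = TRUE,
                  reference_description = maps[[1]]$reference_description)
}

#' Interpolate per-channel values onto a scalp grid
#'
#' Inverse-distance-weighted (power 2) interpolation of one scalar per
#' channel onto a `resolution x resolution` grid over the unit-disc head
#' model; nodes outside the disc are `NA`. Grid values are convex
#' combinations of the inputs, hence bounded by their range, and the node
#' nearest an electrode takes (approximately) its value.
#'
#' @param values numeric vector, one value per montage channel.
#' @param montage a [montage()].
#' @param resolution grid size per axis.
#' @return list with `x`, `y` (grid axes) and `grid`
#'   (`resolution x resolution`, `NA` outside the head).
#' @export
topography_grid <- function(values, montage, resolution = 64) {
  if (length(values) != length(montage$channel_names))
    stop_config("need one value per montage channel (%d)",
                length(montage$channel_names))
  ax <- seq(-1, 1, length.out = resolution)
  gx <- matrix(ax, resolution, resolution)
  gy <- matrix(ax, resolution, resolution, byrow = TRUE)
  grid <- matrix(NA_real_, resolution, resolution)
  inside <- gx^2 + gy^2 <= 1
  px <- montage$positions[, 1]; py <- montage$positions[, 2]
  ii <- which(inside)
  d2 <- outer(gx[ii], px, `-`)^2 + outer(gy[ii], py, `-`)^2
  w <- 1 / pmax(d2, 1e-12)
  grid[ii] <- as.vector((w %*% values) / rowSums(w))
  list(x = ax, y = ax, grid = grid)
}

#' Data-driven ROI extraction from a scaled attribution map
#'
#' Channels are ranked by their time-averaged scaled attribution; the top
#' `top_k` are returned, partitioned into hemispheres by the sign of the
#' montage x coordinate (ties in the ranking break by montage order).
#'
#' @param map a scaled [attribution_map()].
#' @param montage a [montage()] covering the map's channels.
#' @param top_k number of channels to keep.
#' @return `list(right = <labels>, left = <labels>)` (midline channels,
#'   x = 0, count as left by the non-positive-x rule).
#' @export
extract_rois <- function(map, montage, top_k) {
  if (!map$scaled) stop_config("extract_rois expects a scaled map")
  if (top_k > length(map$channel_names))
    stop_config("top_k exceeds channel count")
  score <- rowMeans(map$values)
  ord <- order(-score, seq_along(score))
  top <- map$channel_names[ord[seq_len(top_k)]]
  x <- montage$positions[match(top, montage$channel_names), 1]
  if (anyNA(x)) stop_config("map channels missing from montage")
  list(right = top[x > 0], left = top[x <= 0])
}
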