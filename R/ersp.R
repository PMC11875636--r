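#' Event-related spectral perturbation (ERSP)
#'
#' Complex Morlet time-frequency decomposition (cycles = `max(3, f/2)`),
#' power averaged over trials and over the requested channel set, expressed
#' in dB relative to the trial-averaged power in a pre-cue baseline window:
#' `ERSP(f, t) = 10 log10(P(f, t) / mean_t_baseline P(f, t))`. Epochs are
#' reflection-padded before the transform to tame edge transients; cells
#' closer than three wavelet standard deviations to an epoch edge are
#' flagged invalid in the `valid` mask and excluded from
#' [roi_band_average()].
#'
#' @param epochs a [epochs_set()].
#' @param channel_set channel labels to average over (default: all).
#' @param freqs analysis frequencies in Hz (default 1-30 in 1 Hz steps);
#'   must lie strictly inside (0, Nyquist).
#' @param baseline_window `c(start, end)` seconds, pre-cue; default: the
#'   epochs' own baseline window.
#' @param trials optional trial indices (e.g. one condition).
#' @return object of class `bfn_ersp`: `values_db` (`freqs x times`),
#'   `freqs`, `times`, `valid` (logical mask), `baseline_window`,
#'   `n_trials`, `channel_or_roi`.
#' @export
compute_ersp <- function(epochs, channel_set = NULL, freqs = 1:30,
                         baseline_window = NULL, trials = NULL) {
  fs <- epochs$sampling_rate
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop_config("freqs must lie in (0, Nyquist)")
  baseline_window <- baseline_window %||% epochs$baseline_window
  times <- epochs$times
  bl <- which(times >= baseline_window[1] - 1e-9 &
                times <= baseline_window[2] + 1e-9)
  if (!length(bl)) stop_config("baseline window outside the epoch")
  channel_set <- channel_set %||% epochs$channel_names
  ci <- match(channel_set, epochs$channel_names)
  if (anyNA(ci))
    stop_config("unknown channel(s): %s",
                paste(channel_set[is.na(ci)], collapse = ", "))
  ti <- trials %||% seq_len(dim(epochs$data)[1])
  if (!length(ti)) stop_config("needs at least one trial")

  n <- length(times)
  sig <- max(pmax(3, freqs / 2) / (2 * pi * freqs))       # widest wavelet sd (s)
  # reflection padding of half the widest wavelet support on each side
  pad <- min(n - 1L, ceiling(3 * sig * fs))
  idx <- c((pad + 1):2, 1:n, (n - 1):(n - pad))
  np <- n + 2L * pad
  nf <- stats::nextn(np, c(2, 3, 5))
  fgrid <- c(0:(nf %/% 2), -((nf - nf %/% 2 - 1):1)) * fs / nf

  # columns: all (channel, trial) traces
  m <- matrix(aperm(epochs$data[ti, ci, , drop = FALSE], c(3, 2, 1)), n)
  mp <- rbind(m[idx, , drop = FALSE], matrix(0, nf - np, ncol(m)))
  X <- stats::mvfft(mp)
  P <- matrix(0, length(freqs), n)
  valid <- matrix(TRUE, length(freqs), n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    s_t <- max(3, f0 / 2) / (2 * pi * f0)
    H <- 2 * exp(-((fgrid - f0)^2) * (2 * pi^2 * s_t^2))   # analytic kernel
    W <- stats::mvfft(X * H, inverse = TRUE) / nf
    pw <- Mod(W[pad + seq_len(n), , drop = FALSE])^2
    P[i, ] <- rowMeans(pw)
    margin <- 3 * s_t
    valid[i, ] <- times >= times[1] + margin & times <= times[n] - margin
  }
  base <- rowMeans(P[, bl, drop = FALSE])
  values_db <- 10 * log10(sweep(P, 1, base, `/`))
  structure(list(channel_or_roi = paste(channel_set, collapse = ","),
                 freqs = freqs, times = times, values_db = values_db,
                 valid = valid, baseline_window = baseline_window,
                 n_trials = length(ti)),
            class = "bfn_ersp")
}

#' @export
print.bfn_ersp <- function(x, ...) {
  cat(sprintf("<bfn_ersp> %d freqs x %d times, %d trials, baseline [%.2f, %.2f] s\n",
              length(x$freqs), length(x$times), x$n_trials,
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Mean ERSP over a band and time window
#'
#' Averages `values_db` over the frequency rows inside the band and the
#' time columns inside the window, using only cells outside the wavelet
#' edge margins.
#'
#' @param map a `bfn_ersp` from [compute_ersp()].
#' @param band a [band_spec()].
#' @param window `c(start, end)` seconds.
#' @return mean dB (scalar).
#' @export
roi_band_average <- function(map, band, window) {
  fi <- which(map$freqs >= band$low & map$freqs <= band$high)
  tj <- which(map$times >= window[1] - 1e-9 & map$times <= window[2] + 1e-9)
  if (!length(fi) || !length(tj)) stop_config("empty band/window selection")
  v <- map$values_db[fi, tj, drop = FALSE]
  ok <- map$valid[fi, tj, drop = FALSE]
  if (!any(ok)) stop_config("no valid (non-edge) cells in the selection")
  mean(v[ok])
}

#' Paired bootstrap test on per-subject differences
#'
#' Resamples the paired differences `d = a - b` with replacement `n_boot`
#' times; the two-sided p value is
#' `2 * min(mean(boot_means <= 0), mean(boot_means >= 0))`, floored at
#' `1/n_boot` and capped at 1. Deterministic given `seed`. When every
#' difference is zero the test is a no-op (p = 1).
#'
#' @param a,b equal-length per-subject values (N >= 2).
#' @param n_boot bootstrap resamples (values below 100 warn).
#' @param seed RNG seed.
#' @return object of class `bfn_stat` (`statistic` = mean difference).
#' @export
bootstrap_paired_test <- function(a, b, n_boot = 2000, seed = 1L) {
  n <- length(a)
  if (length(b) != n || n < 2) stop_config("a and b must have equal length >= 2")
  if (n_boot < 100) warning("n_boot < 100 gives a very coarse p value")
  d <- a - b
  if (all(d == 0))
    return(stat_result("paired bootstrap", 0, NA, 1, n = n))
  bm <- with_seed(derive_seed(seed, "boot"), {
    rowMeans(matrix(d[sample.int(n, n_boot * n, replace = TRUE)], n_boot, n))
  })
  p <- 2 * min(mean(bm <= 0), mean(bm >= 0))
  p <- min(1, max(p, 1 / n_boot))
  stat_result("paired bootstrap", mean(d), NA, p, n = n)
}

#' Bonferroni correction
#'
#' @param p_values vector of p values in `[0, 1]`.
#' @param m number of tests (defaults to `length(p_values)`; must be at
#'   least that).
#' @return adjusted p values (`p * m`, capped at 1).
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop_config("p values outside [0, 1]")
  if (m < length(p_values)) stop_config("m must be >= number of tests")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}
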