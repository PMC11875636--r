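#' Configuration for the synthetic motor-imagery EEG simulator
#'
#' The simulator emulates a two-condition single-trial motor-imagery study:
#' every trial is per-channel 1/f ("pink") background noise plus band-limited
#' oscillatory sources projected onto channel subsets. Condition effects are
#' multiplicative amplitude modulations of source envelopes inside the MI
#' window (raised-cosine ramps), planted with known dB magnitudes:
#' natural-thumb trials (label 0) receive a delta/theta power increase
#' confined to the ten frontal ROI channels, supernumerary-thumb trials
#' (label 1) receive a broad alpha power decrease over centro-parietal
#' channels. Between-subject variability multiplies the planted dB values by
#' a lognormal factor drawn once per subject.
#'
#' @param n_subjects number of subjects in the cohort (default 16).
#' @param trials_per_condition balanced trials per condition and subject.
#' @param sampling_rate Hz; must be at least four times the highest source
#'   band edge.
#' @param epoch_window `c(baseline_start, mi_start, mi_end)` seconds; the
#'   cue is at `mi_start = 0`.
#' @param noise `list(exponent, amplitude)`: 1/f^exponent spectral slope and
#'   overall noise standard deviation per channel.
#' @param sources list of sources, each
#'   `list(band = band_spec, channels = labels, amplitude = sd)`; `NULL`
#'   installs the default frontal delta, frontal theta and broad alpha
#'   sources with amplitudes giving roughly 10:1 in-band source-to-noise
#'   power at the target channels.
#' @param nt_ers_db planted delta/theta power increase (dB) during MI for
#'   natural-thumb trials (event-related synchronisation).
#' @param st_erd_db planted alpha power change (dB) during MI for
#'   supernumerary-thumb trials; negative = desynchronisation.
#' @param subject_sd standard deviation of the lognormal per-subject
#'   multiplier applied to the planted dB effects.
#' @param montage the electrode [montage()]; defaults to
#'   [make_default_montage()].
#' @param seed master seed; every random stage derives its own stream from
#'   it, so a given `(config, seed)` reproduces the cohort bit-identically.
#' @return object of class `bfn_simconfig`.
#' @export
simulation_config <- function(n_subjects = 16,
                              trials_per_condition = 60,
                              sampling_rate = 128,
                              epoch_window = c(-1, 0, 4),
                              noise = list(exponent = 1, amplitude = 1),
                              sources = NULL,
                              nt_ers_db = 3,
                              st_erd_db = -3,
                              subject_sd = 0.2,
                              montage = make_default_montage(),
                              seed = 1L) {
  if (n_subjects < 1 || trials_per_condition < 1)
    stop_config("n_subjects and trials_per_condition must be >= 1")
  if (!is.finite(nt_ers_db) || !is.finite(st_erd_db))
    stop_config("effect dB values must be finite")
  if (subject_sd < 0) stop_config("subject_sd must be >= 0")
  if (length(epoch_window) != 3 || any(diff(epoch_window) <= 0) ||
      abs(epoch_window[2]) > 1e-12)
    stop_config("epoch_window must be (baseline_start < 0 = mi_start < mi_end)")
  if (is.null(sources)) {
    frontal <- roi_channels(montage)
    broad <- grep("^(C|CP|P)[0-9z]+$|^T[78]$|^TP[78]$",
                  montage$channel_names, value = TRUE)
    b <- default_bands()
    sources <- list(
      list(band = b$delta, channels = frontal, amplitude = 1.7,
           role = "nt_ers"),
      list(band = b$theta, channels = frontal, amplitude = 1.2,
           role = "nt_ers"),
      list(band = b$alpha, channels = broad, amplitude = 0.9,
           role = "st_erd"))
  }
  hi <- max(vapply(sources, function(s) s$band$high, numeric(1)))
  if (sampling_rate < 4 * hi)
    stop_config("sampling_rate must be >= 4 x highest source band edge (%g)", hi)
  for (s in sources) {
    bad <- setdiff(s$channels, montage$channel_names)
    if (length(bad))
      stop_config("source channels not in montage: %s", paste(bad, collapse = ", "))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 sampling_rate = sampling_rate,
                 epoch_window = epoch_window,
                 noise = noise, sources = sources,
                 nt_ers_db = nt_ers_db, st_erd_db = st_erd_db,
                 subject_sd = subject_sd, montage = montage,
                 seed = as.integer(seed)),
            class = "bfn_simconfig")
}

# Spectral amplitude shaping vector for an rfft-style two-sided grid.
# Normalised so that filtering unit white noise keeps unit variance in
# expectation; effects planted on top therefore stay exactly multiplicative.
.spec_shape <- function(n, fs, shape_fun) {
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) * fs / n
  h <- shape_fun(abs(f))
  h / sqrt(mean(h^2))
}

# n x m matrix of coloured Gaussian noise columns with spectral amplitude
# shape `h` (length n), unit variance in expectation.
.coloured_noise <- function(n, m, h) {
  w <- matrix(stats::rnorm(n * m), n, m)
  Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n
}

.pink_shape <- function(n, fs, beta) {
  .spec_shape(n, fs, function(af) ifelse(af < 0.5, 0, (pmax(af, 0.5))^(-beta / 2)))
}

.band_shape <- function(n, fs, band, edge = 0.5) {
  .spec_shape(n, fs, function(af) {
    up <- (af - (band$low - edge)) / edge
    dn <- ((band$high + edge) - af) / edge
    pmin(1, pmax(0, pmin(up, dn)))
  })
}

# Raised-cosine MI-window gain envelope: 1 outside the MI window, ramping
# over `ramp` seconds to `gain` inside it.
.mi_envelope <- function(times, mi_start, mi_end, gain, ramp = 0.25) {
  g <- rep(1, length(times))
  rise <- times >= mi_start & times < mi_start + ramp
  g[rise] <- 1 + (gain - 1) * (1 - cos(pi * (times[rise] - mi_start) / ramp)) / 2
  g[times >= mi_start + ramp & times < mi_end] <- gain
  fall <- times >= mi_end - ramp & times < mi_end
  if (mi_end - ramp > mi_start + ramp)
    g[fall] <- 1 + (gain - 1) * (1 + cos(pi * (times[fall] - (mi_end - ramp)) / ramp)) / 2
  g
}

.subject_effect_multiplier <- function(config, subject_index) {
  with_seed(derive_seed(config$seed, "subject-effect", subject_index),
            exp(stats::rnorm(1, 0, config$subject_sd)))
}

#' Generate one synthetic subject
#'
#' Deterministic in `(config, config$seed, subject_index)`; the subject's
#' random stream is derived from the master seed so the same subject can be
#' regenerated standalone or as part of [generate_cohort()].
#'
#' @param config a [simulation_config()].
#' @param subject_index 1-based subject index (`<= config$n_subjects`).
#' @return a [epochs_set()] with balanced labels
#'   (`trials_per_condition` per condition, natural-thumb trials first).
#' @export
generate_subject <- function(config, subject_index) {
  if (!inherits(config, "bfn_simconfig")) stop_config("config must be a bfn_simconfig")
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop_config("subject_index out of range")
  fs <- config$sampling_rate
  ew <- config$epoch_window
  times <- seq(ew[1], ew[3] - 1 / fs, by = 1 / fs)
  n <- length(times)
  chans <- config$montage$channel_names
  C <- length(chans)
  tpc <- config$trials_per_condition
  ntr <- 2L * tpc
  labels <- rep(c(0L, 1L), each = tpc)

  eff_mult <- .subject_effect_multiplier(config, subject_index)
  nt_gain <- 10^((config$nt_ers_db * eff_mult) / 20)   # amplitude multiplier
  st_gain <- 10^((config$st_erd_db * eff_mult) / 20)

  data <- with_seed(derive_seed(config$seed, "subject-data", subject_index), {
    pink <- .pink_shape(n, fs, config$noise$exponent)
    x <- array(.coloured_noise(n, C * ntr, pink) * config$noise$amplitude,
               dim = c(n, C, ntr))
    for (s in config$sources) {
      sh <- .band_shape(n, fs, s$band)
      src <- .coloured_noise(n, ntr, sh) * s$amplitude        # n x trials
      gain <- if (identical(s$role %||% "", "nt_ers")) nt_gain
              else if (identical(s$role %||% "", "st_erd")) st_gain
              else 1
      if (gain != 1) {
        env <- .mi_envelope(times, ew[2], ew[3], gain)
        mod <- if (identical(s$role, "nt_ers")) labels == 0L else labels == 1L
        src[, mod] <- src[, mod] * env
      }
      ci <- match(s$channels, chans)
      x[, ci, ] <- x[, ci, ] +
        aperm(array(src, dim = c(n, ntr, length(ci))), c(1, 3, 2))
    }
    aperm(x, c(3, 2, 1))                                      # trials x ch x samp
  })
  epochs_set(subject_id = sprintf("S%02d", subject_index),
             data = data, sampling_rate = fs, channel_names = chans,
             times = times, labels = labels,
             baseline_window = c(ew[1], ew[2]))
}

#' Generate a full synthetic cohort
#'
#' @param config a [simulation_config()].
#' @return list of [epochs_set()] objects with distinct subject ids;
#'   per-subject effect multipliers are drawn from streams derived from the
#'   master seed, so the cohort is bit-reproducible.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(i) generate_subject(config, i))
}
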