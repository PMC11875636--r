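# Shared fixtures, built in code. A 12-channel montage (the 10 frontal ROI
# channels plus two central ones) keeps simulation-heavy tests fast while
# preserving the ROI structure the package analyses.
options(bandfocus.quiet = TRUE)

small_montage <- function() {
  full <- make_default_montage()
  keep <- c(roi_channels(full), "C3", "C4")
  montage(keep, full$positions[match(keep, full$channel_names), ],
          rois = full$rois)
}

small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 2, trials_per_condition = 20,
                   sampling_rate = 64, epoch_window = c(-1, 0, 3),
                   montage = small_montage(), seed = 101)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# memoised tiny strong-effect cohort for expensive end-to-end tests
.fixture_env <- new.env()
tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(
      small_sim_config(n_subjects = 3, trials_per_condition = 30, seed = 77))
  .fixture_env$cohort
}

# Per-trial band power (variance of the band-passed signal) over a channel
# subset and time window: the simple quadratic oracle used to probe planted
# effects without going through the ERSP module.
trial_band_power <- function(epochs, band, channels, window) {
  x <- crop_epochs(epochs, channels = channels, window = window)
  f <- bandpass_filter(x$data, epochs$sampling_rate, band)
  apply(f, 1, function(tr) mean(tr^2))
}

published_table <- function() {
  utils::read.csv(system.file("extdata", "published_loso_accuracy.csv",
                              package = "bandfocus"))
}
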