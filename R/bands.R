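#' Frequency band specification
#'
#' @param name band label (e.g. `"delta"`).
#' @param low,high passband edges in Hz; `0 < low < high` is required, and
#'   `high` must stay below the Nyquist frequency of any data the band is
#'   applied to (checked at filter time).
#' @return An object of class `bfn_band`.
#' @export
band_spec <- function(name, low, high) {
  if (!is.character(name) || length(name) != 1)
    stop_config("band name must be a single string")
  if (!(is.finite(low) && is.finite(high) && low > 0 && high > low))
    stop_config("band edges must satisfy 0 < low < high (got %s, %s)",
                format(low), format(high))
  structure(list(name = name, low = low, high = high), class = "bfn_band")
}

#' @export
print.bfn_band <- function(x, ...) {
  cat(sprintf("<bfn_band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Canonical delta/theta/alpha bands
#'
#' Delta 1-4 Hz and theta 4-8 Hz follow conventional boundaries; alpha is
#' 9-13 Hz, the range in which motor-imagery desynchronisation is classically
#' observed at the motor cortex.
#'
#' @return named list of [band_spec()] objects (`delta`, `theta`, `alpha`).
#' @export
default_bands <- function() {
  list(delta = band_spec("delta", 1, 4),
       theta = band_spec("theta", 4, 8),
       alpha = band_spec("alpha", 9, 13))
}
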