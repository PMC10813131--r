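#' Frequency band specification
#'
#' A band is a named half-open frequency interval used for narrowband
#' filtering and PLV estimation.
#'
#' @param name Band name (e.g. `"alpha"`).
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 13)
#' @export
band_spec <- function(name, low_hz, high_hz) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_invalid("band name must be a non-empty string")
  low_hz <- as.numeric(low_hz); high_hz <- as.numeric(high_hz)
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 || low_hz >= high_hz)
    stop_invalid("band edges must satisfy 0 < low_hz < high_hz (got %g, %g)",
                 low_hz, high_hz)
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_spec")
}

#' Canonical EEG frequency bands
#'
#' The five conventional bands: delta (1-4 Hz), theta (4-8 Hz),
#' alpha (8-13 Hz), beta (13-30 Hz), gamma (30-50 Hz). Adjacent bands abut,
#' tiling 1-50 Hz without gaps.
#'
#' @return Named list of [band_spec()] objects.
#' @export
canonical_bands <- function() {
  list(
    delta = band_spec("delta", 1, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 13),
    beta  = band_spec("beta", 13, 30),
    gamma = band_spec("gamma", 30, 50)
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$low_hz, x$high_hz))
  invisible(x)
}

# Resolve a band given by name, band_spec, or list of either.
as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1L) {
    cb <- canonical_bands()
    if (!band %in% names(cb))
      stop_invalid("unknown band '%s' (canonical: %s)", band,
                   paste(names(cb), collapse = ", "))
    return(cb[[band]])
  }
  stop_invalid("cannot interpret band of class %s", class(band)[1L])
}
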