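# Frequency band definitions over the 1-49 Hz analysis range (1-Hz bins).

#' Define a frequency band
#'
#' A band is a named set of inclusive 1-Hz frequency bins within the
#' 1-49 Hz analysis range. Contiguous bands are given by `lo`/`hi`;
#' non-contiguous bands (the beta band spans 14-16 and 22-26 Hz) can be
#' given explicitly via `bins`.
#'
#' @param name Band name.
#' @param lo,hi Inclusive bounds in Hz (integers, 1 <= lo <= hi <= 49).
#' @param bins Optional explicit integer bin vector overriding `lo`/`hi`.
#' @return A `band_definition` object.
#' @export
band_definition <- function(name, lo = NULL, hi = NULL, bins = NULL) {
  if (is.null(bins)) {
    lo <- check_number(lo, "lo", 1, 49)
    hi <- check_number(hi, "hi", lo, 49)
    bins <- seq.int(lo, hi)
  } else {
    bins <- sort(unique(as.integer(bins)))
    if (!length(bins)) stop_oscdev("band '%s' has no bins", name)
    if (any(bins < 1L | bins > 49L))
      stop_oscdev("band '%s' has bins outside 1-49 Hz", name)
  }
  structure(list(name = name, lo_hz = min(bins), hi_hz = max(bins),
                 bins = bins),
            class = "band_definition")
}

#' Canonical analysis bands
#'
#' The bands in which age effects are tested: delta 1-3 Hz (power declines
#' with age), theta 5-9 Hz (phase coupling declines with age), and beta
#' 14-16 Hz plus 22-26 Hz (power rises with age).
#'
#' @return Named list of [band_definition()] objects: `delta`, `theta`,
#'   `beta` (8 non-contiguous bins), `beta_low`, `beta_high`.
#' @export
standard_bands <- function() {
  list(
    delta = band_definition("delta", 1, 3),
    theta = band_definition("theta", 5, 9),
    beta = band_definition("beta", bins = c(14:16, 22:26)),
    beta_low = band_definition("beta_low", 14, 16),
    beta_high = band_definition("beta_high", 22, 26)
  )
}

#' Five-hertz bin partition of the 1-49 Hz range
#'
#' Bins 1-5, 6-10, ..., 41-45 Hz and a final 46-49 Hz bin (4 bins wide),
#' used for the frequency-resolved anterior-to-posterior gradient profile.
#' The 6-10 Hz bin is the reference for slope-difference tests.
#'
#' @return Named list of ten [band_definition()] objects.
#' @export
five_hz_bins <- function() {
  lows <- seq(1, 46, by = 5)
  bins <- lapply(lows, function(lo) {
    hi <- min(lo + 4, 49)
    band_definition(sprintf("%d-%d", lo, hi), lo, hi)
  })
  names(bins) <- vapply(bins, `[[`, "", "name")
  bins
}

#' @method print band_definition
#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("band '%s': %s Hz (%d bins)\n", x$name,
              paste(range(x$bins), collapse = "-"), length(x$bins)))
  invisible(x)
}
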