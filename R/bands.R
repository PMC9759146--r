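#' Canonical MEG frequency bands
#'
#' The seven analysis bands used throughout the pipeline: delta (1-4 Hz),
#' theta (4-8), alpha (8-12), beta (12-30), gamma (30-80), ripple (80-250)
#' and fast ripple (250-500). High-frequency oscillation bands (ripple and
#' fast ripple) require a sampling rate above 1000 Hz to be representable.
#'
#' @param names Optional character vector restricting the result to a subset
#'   of band names (order preserved as given).
#' @return A tibble with columns `band` (factor in canonical order),
#'   `lo` and `hi` (band edges in Hz).
#' @examples
#' meg_bands()
#' meg_bands(c("alpha", "beta"))
#' @export
meg_bands <- function(names = NULL) {
  bands <- tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma", "ripple", "fast_ripple"),
    lo = c(1, 4, 8, 12, 30, 80, 250),
    hi = c(4, 8, 12, 30, 80, 250, 500)
  )
  if (!is.null(names)) {
    unknown <- setdiff(names, bands$band)
    if (length(unknown)) {
      abort(paste0("Unknown band(s): ", paste(unknown, collapse = ", ")))
    }
    bands <- bands[match(names, bands$band), ]
  }
  bands$band <- factor(bands$band, levels = c(
    "delta", "theta", "alpha", "beta", "gamma", "ripple", "fast_ripple"
  ))
  bands
}

# Validate a one-row band definition against a sampling rate.
check_band <- function(band, fs) {
  stopifnot(is.data.frame(band), nrow(band) == 1)
  if (!(band$lo > 0 && band$lo < band$hi)) {
    abort(sprintf("Invalid band edges [%g, %g] Hz", band$lo, band$hi))
  }
  if (band$hi >= fs / 2) {
    abort(sprintf(
      "Band edge %g Hz is at or above the Nyquist frequency (%g Hz)",
      band$hi, fs / 2
    ))
  }
  invisible(band)
}
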