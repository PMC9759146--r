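#' Power-line notch filter
#'
#' Removes the mains interference component with a biquad IIR notch (Q = 30)
#' applied forward and backward (zero phase) on every channel.
#'
#' @param rec A `meg_recording`.
#' @param freq Notch centre frequency in Hz (default 50).
#' @param Q Quality factor; the -3 dB width is `freq / Q`.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, freq = 50, Q = 30) {
  stopifnot(inherits(rec, "meg_recording"))
  if (freq >= rec$fs / 2) {
    abort(sprintf("Notch frequency %g Hz is not below Nyquist (%g Hz)", freq, rec$fs / 2))
  }
  cf <- notch_coefficients(freq, rec$fs, Q)
  rec$data <- apply(rec$data, 2, function(x) {
    signal::filtfilt(signal::Arma(b = cf$b, a = cf$a), x)
  })
  rec
}

#' Zero-phase band-pass decomposition
#'
#' Restricts a recording to one analysis band using a zero-phase
#' frequency-domain filter with raised-cosine edges. Out-of-band components
#' an octave or more away are suppressed essentially completely.
#'
#' @param rec A `meg_recording`.
#' @param band A band name (see [meg_bands()]) or a one-row data frame with
#'   columns `band`, `lo`, `hi`.
#' @return The band-limited recording.
#' @export
bandpass <- function(rec, band) {
  stopifnot(inherits(rec, "meg_recording"))
  if (is.character(band)) band <- meg_bands(band)
  check_band(band, rec$fs)
  rec$data <- fft_bandpass(rec$data, rec$fs, band$lo, band$hi)
  rec
}

# Turn a logical per-sample flag vector into merged, padded intervals.
samples_to_intervals <- function(flagged, fs, pad_s, kind) {
  if (!any(flagged)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(), kind = character()))
  }
  idx <- which(flagged)
  t0 <- (idx - 1) / fs - pad_s
  t1 <- idx / fs + pad_s
  merge_intervals(tibble::tibble(
    start_s = pmax(t0, 0),
    end_s = pmin(t1, length(flagged) / fs),
    kind = kind
  ))
}

#' Merge overlapping flagged intervals
#'
#' @param intervals Tibble with columns `start_s`, `end_s` (and optionally
#'   `kind`; merged intervals concatenate distinct kinds with `"+"`).
#' @return Tibble of disjoint intervals sorted by start; merging is
#'   idempotent.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) <= 1) {
    return(intervals)
  }
  iv <- dplyr::arrange(intervals, .data$start_s, .data$end_s)
  has_kind <- "kind" %in% names(iv)
  out <- iv[1, ]
  for (k in seq(2, nrow(iv))) {
    last <- nrow(out)
    if (iv$start_s[k] <= out$end_s[last]) {
      out$end_s[last] <- max(out$end_s[last], iv$end_s[k])
      if (has_kind && !grepl(iv$kind[k], out$kind[last], fixed = TRUE)) {
        out$kind[last] <- paste(out$kind[last], iv$kind[k], sep = "+")
      }
    } else {
      out <- dplyr::bind_rows(out, iv[k, ])
    }
  }
  out
}

#' Flag high-amplitude artifact intervals
#'
#' Implements the amplitude-exclusion rule: any sample whose absolute value
#' exceeds the threshold on any channel is flagged, padded by `pad_s` on each
#' side, and overlapping flags are merged.
#'
#' @param rec A `meg_recording` (amplitudes in pT).
#' @param threshold Exclusion threshold in pT (default 6).
#' @param pad_s Padding in seconds around each flagged sample (default 0.5).
#' @return Tibble of intervals (`start_s`, `end_s`, `kind = "artifact"`).
#' @export
detect_artifacts <- function(rec, threshold = 6, pad_s = 0.5) {
  stopifnot(inherits(rec, "meg_recording"), threshold > 0)
  flagged <- apply(abs(rec$data) > threshold, 1, any)
  samples_to_intervals(flagged, rec$fs, pad_s, "artifact")
}

#' Flag epileptiform spike intervals
#'
#' Automated surrogate for visual spike marking: the recording is restricted
#' to the 1-70 Hz range, each channel is converted to robust z-scores
#' (median / MAD), and samples exceeding `z_thresh` on any channel are
#' flagged, padded and merged.
#'
#' @param rec A `meg_recording` of at least 2 s.
#' @param z_thresh Robust z threshold (default 6).
#' @param pad_s Padding in seconds (default 0.5).
#' @param lo,hi Detection band in Hz (default 1-70; `hi` is clipped below
#'   Nyquist for low sampling rates).
#' @return Tibble of intervals (`start_s`, `end_s`, `kind = "spike"`).
#' @export
flag_spikes <- function(rec, z_thresh = 6, pad_s = 0.5, lo = 1, hi = 70) {
  stopifnot(inherits(rec, "meg_recording"))
  if (recording_duration(rec) < 2) abort("Recording must be at least 2 s for spike flagging")
  hi <- min(hi, 0.95 * rec$fs / 2)
  x <- fft_bandpass(rec$data, rec$fs, lo, hi)
  flagged <- rep(FALSE, nrow(x))
  for (ch in seq_len(ncol(x))) {
    s <- mad(x[, ch])
    if (s == 0) {
      warn(sprintf("Channel %d has zero variance; skipped in spike flagging", ch))
      next
    }
    flagged <- flagged | (abs(x[, ch] - median(x[, ch])) / s > z_thresh)
  }
  samples_to_intervals(flagged, rec$fs, pad_s, "spike")
}

#' Select the earliest clean analysis segment
#'
#' Finds the earliest window of exactly `length_s` seconds that overlaps no
#' flagged interval and extracts it as the analysis segment (default 60 s,
#' the spike-free fragment length used for connectivity).
#'
#' @param rec A `meg_recording`.
#' @param flags Tibble of flagged intervals (e.g. the row-bound output of
#'   [detect_artifacts()] and [flag_spikes()]); `NULL` for none.
#' @param length_s Segment length in seconds (default 60).
#' @return An object of class `meg_segment`: fields `data` (K x N matrix),
#'   `fs`, `band` (`"broadband"` here), `start_s`, `K`, `node_labels`,
#'   `node_roles`.
#' @export
select_clean_segment <- function(rec, flags = NULL, length_s = 60) {
  stopifnot(inherits(rec, "meg_recording"))
  dur <- recording_duration(rec)
  if (dur < length_s) {
    abort(sprintf("Recording (%.3g s) is shorter than the requested %g s segment", dur, length_s))
  }
  if (is.null(flags) || nrow(flags) == 0) {
    start <- 0
  } else {
    flags <- merge_intervals(flags)
    candidates <- sort(unique(c(0, flags$end_s)))
    candidates <- candidates[candidates + length_s <= dur + 1e-9]
    ok <- purrr::map_lgl(candidates, function(t0) {
      !any(flags$start_s < t0 + length_s & flags$end_s > t0)
    })
    if (!any(ok)) abort("No clean segment of the requested length exists")
    start <- candidates[which(ok)[1]]
  }
  i0 <- floor(start * rec$fs) + 1L
  K <- round(length_s * rec$fs)
  structure(
    list(
      data = rec$data[i0:(i0 + K - 1L), , drop = FALSE],
      fs = rec$fs, band = "broadband", start_s = start, K = K,
      node_labels = rec$node_labels, node_roles = rec$node_roles
    ),
    class = "meg_segment"
  )
}

#' @export
print.meg_segment <- function(x, ...) {
  cat(sprintf(
    "<meg_segment> %d nodes, K = %d samples @ %g Hz, band %s, start %.3g s\n",
    ncol(x$data), x$K, x$fs, x$band, x$start_s
  ))
  invisible(x)
}

#' Band-limit a clean segment
#'
#' @param seg A `meg_segment`.
#' @param band Band name or one-row band definition.
#' @return The segment filtered to the band, with `band` updated.
#' @export
segment_bandpass <- function(seg, band) {
  stopifnot(inherits(seg, "meg_segment"))
  if (is.character(band)) band <- meg_bands(band)
  check_band(band, seg$fs)
  seg$data <- fft_bandpass(seg$data, seg$fs, band$lo, band$hi)
  seg$band <- as.character(band$band)
  seg
}
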