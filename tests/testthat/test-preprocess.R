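sine_recording <- function(freq, fs = 1000, duration = 10, amp = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  meg_recording(cbind(amp * sin(2 * pi * freq * t)), fs)
}

rms <- function(x) sqrt(mean(x^2))

test_that("the notch removes mains frequency and spares the passband", {
  # measure over the steady-state interior; filtfilt start-up transients at
  # the record edges are not part of the rejection contract
  mid <- 1001:9000
  mains <- sine_recording(50)
  expect_lt(rms(notch_filter(mains)$data[mid, ]) / rms(mains$data[mid, ]), 0.03)
  nearby <- sine_recording(10)
  expect_equal(
    rms(notch_filter(nearby)$data) / rms(nearby$data), 1,
    tolerance = 0.05
  )
  zeros <- meg_recording(matrix(0, 1000, 2), 1000)
  expect_equal(notch_filter(zeros)$data, zeros$data, ignore_attr = TRUE)
  expect_error(notch_filter(sine_recording(10, fs = 80)), "Nyquist")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  tone10 <- sine_recording(10)
  expect_gt(rms(bandpass(tone10, "alpha")$data) / rms(tone10$data), 0.95)
  # 10 Hz is three octaves below the ripple band: >= 20 dB down
  expect_lt(rms(bandpass(tone10, "ripple")$data) / rms(tone10$data), 0.1)
  zeros <- meg_recording(matrix(0, 1000, 1), 1000)
  expect_equal(bandpass(zeros, "alpha")$data, zeros$data, ignore_attr = TRUE)
  expect_error(bandpass(tone10, "fast_ripple"), "Nyquist")
})

test_that("filtering is zero-phase: a symmetric pulse keeps its centre of mass", {
  fs <- 1000
  n <- 4000
  x <- exp(-((seq_len(n) - 2000)^2) / (2 * 30^2))
  rec <- meg_recording(cbind(x), fs)
  com <- function(v) sum(seq_along(v) * v^2) / sum(v^2)
  filtered <- bandpass(rec, meg_bands("gamma"))
  expect_lt(abs(com(filtered$data[, 1]) - com(x)), 1)
  notched <- notch_filter(rec)
  expect_lt(abs(com(notched$data[, 1]) - com(x)), 1)
})

test_that("amplitude artifacts are flagged per the 6 pT rule with padding", {
  fs <- 100
  data <- matrix(0, 60 * fs, 2)
  rec_ok <- meg_recording(data + 5.9, fs)
  expect_equal(nrow(detect_artifacts(rec_ok)), 0)
  data[10 * fs, 1] <- 7
  rec_bad <- meg_recording(data, fs)
  flags <- detect_artifacts(rec_bad)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$start_s, 9.5, tolerance = 0.02)
  expect_equal(flags$end_s, 10.5, tolerance = 0.02)
  expect_equal(nrow(detect_artifacts(meg_recording(matrix(0, 100, 1), 100))), 0)
})

test_that("interval merging is idempotent and joins overlaps", {
  iv <- tibble::tibble(
    start_s = c(5, 1, 2, 9), end_s = c(6, 3, 4, 10),
    kind = c("spike", "artifact", "spike", "spike")
  )
  merged <- merge_intervals(iv)
  expect_equal(merged$start_s, c(1, 5, 9))
  expect_equal(merged$end_s, c(4, 6, 10))
  expect_identical(merge_intervals(merged), merged)
})

test_that("robust z-score flagging catches large transients, rarely pure noise", {
  cfg <- pair_config(0, fs = 200, duration = 30)
  rec <- generate_recording(cfg, seed = 7)
  spiked <- inject_spikes(rec, rate = 4, amplitude = 12 * 0.5, seed = 3)
  flags <- flag_spikes(spiked)
  expect_gt(nrow(flags), 0)
  # every injected event lies inside a flagged interval
  for (k in seq_len(nrow(spiked$annotations))) {
    on <- spiked$annotations$onset_s[k]
    expect_true(any(flags$start_s <= on & flags$end_s >= on + spiked$annotations$duration_s[k]))
  }
  # false-positive rate on stationary noise across seeds
  n_flagged <- sum(vapply(1:60, function(s) {
    nrow(flag_spikes(generate_recording(cfg, seed = 1000 + s))) > 0
  }, logical(1)))
  expect_lte(n_flagged, 2)
  zeros <- meg_recording(matrix(0, 500, 1), 100)
  expect_warning(fl <- flag_spikes(zeros), "zero variance")
  expect_equal(nrow(fl), 0)
})

test_that("the earliest clean segment of exactly 60 s is selected", {
  fs <- 100
  rec <- meg_recording(matrix(rnorm(120 * fs * 2), ncol = 2), fs)
  seg0 <- select_clean_segment(rec, NULL, 60)
  expect_equal(seg0$start_s, 0)
  expect_equal(seg0$K, 60 * fs)
  late <- tibble::tibble(start_s = 70, end_s = 71, kind = "spike")
  expect_equal(select_clean_segment(rec, late, 60)$start_s, 0)
  early <- tibble::tibble(start_s = 10, end_s = 11, kind = "spike")
  seg <- select_clean_segment(rec, early, 60)
  expect_equal(seg$start_s, 11)
  everywhere <- tibble::tibble(start_s = c(0, 50), end_s = c(45, 119), kind = "spike")
  expect_error(select_clean_segment(rec, everywhere, 60), "No clean segment")
  expect_error(select_clean_segment(rec, NULL, 200), "shorter")
})

test_that("selected segments never overlap flags on random flag sets", {
  fs <- 50
  rec <- meg_recording(matrix(0, 200 * fs, 1), fs)
  set.seed(42)
  for (trial in 1:25) {
    n_flags <- sample(0:4, 1)
    starts <- runif(n_flags, 0, 195)
    flags <- tibble::tibble(
      start_s = starts, end_s = starts + runif(n_flags, 0.1, 5), kind = "spike"
    )
    seg <- tryCatch(select_clean_segment(rec, flags, 60), error = function(e) NULL)
    if (is.null(seg)) next
    overlap <- any(flags$start_s < seg$start_s + 60 & flags$end_s > seg$start_s)
    expect_false(overlap)
  }
})
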