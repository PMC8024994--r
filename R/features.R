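#' Detect the contact onset in a touch trace
#'
#' Onset is the first index at which the trace exceeds a noise-floor multiple
#' for at least 5 consecutive samples. The noise floor is the standard
#' deviation of the pre-contact head of the trace (first `head_n` samples),
#' with a small absolute floor so noiseless traces are handled.
#'
#' @param trace Numeric touch trace (volts).
#' @param k Threshold multiple of the noise floor (default 4).
#' @param head_n Samples used to estimate the noise floor (default 30).
#' @param run Consecutive supra-threshold samples required (default 5).
#' @return Integer onset index.
#' @export
detect_onset <- function(trace, k = 4, head_n = 30, run = 5) {
  if (!is.numeric(trace) || length(trace) < head_n + run) {
    abort_invalid("`trace` is too short for onset detection")
  }
  floor_sd <- max(sd(trace[seq_len(head_n)]), 1e-9 * max(abs(trace)), 1e-12)
  above <- abs(trace) > k * floor_sd
  # first index starting a run of `run` TRUEs
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run)
  if (length(hit) == 0L) {
    abort_estimation("no contact onset detected (flat trace)")
  }
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Estimate the initial slope of a touch transient
#'
#' Least-squares slope of the rise segment from contact onset to the first
#' peak of the trace. The slope is proportional to durometer hardness at
#' fixed contact force, so it serves as a relative hardness readout.
#'
#' @param touch_trace Numeric touch trace (volts).
#' @param sample_rate Samples per second (default 1000).
#' @param onset Optional onset index; detected with [detect_onset()] if `NULL`.
#' @return Slope in volts/second.
#' @export
#' @examples
#' ramp <- c(rep(0, 50), seq(0, 1, length.out = 101)[-1], rep(1, 50))
#' estimate_touch_slope(ramp, onset = 51)
estimate_touch_slope <- function(touch_trace, sample_rate = 1000, onset = NULL) {
  onset <- onset %||% detect_onset(touch_trace)
  seg <- touch_trace[onset:length(touch_trace)]
  # end of the rise = first sample reaching 95% of the segment maximum, so a
  # noisy plateau after the peak does not flatten the fitted slope
  peak <- which(seg >= 0.95 * max(seg))[1]
  if (is.na(peak) || peak < 3L) {
    abort_estimation("rise segment too short to fit a slope")
  }
  y <- seg[seq_len(peak)]
  t <- (seq_len(peak) - 1) / sample_rate
  # least-squares slope through the rise
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# prominence-based peak indices used by the pitch estimator; min_dist keeps
# one peak per texture period once the period scale is known
find_signal_peaks <- function(trace, k = 1, min_dist = 2) {
  thr <- k * sd(trace)
  p <- tryCatch(
    pracma::findpeaks(trace, minpeakheight = thr,
      minpeakdistance = max(2, min_dist), zero = "+"),
    error = function(e) NULL
  )
  if (is.null(p)) integer(0) else sort(p[, 2])
}

# moving-average smoother (odd width), edges handled by partial windows
smooth_ma <- function(x, width) {
  if (width < 2) return(x)
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2)) |>
    (\(y) ifelse(is.na(y), x, y))()
}

#' Estimate surface pattern pitch from a sliding signal
#'
#' The spatial period of the surface texture equals sliding velocity times
#' the time interval between successive signal peaks: a 0.01 s interval at
#' 4 cm/s corresponds to a 400 um pitch. The estimator detects peaks above
#' `k` trace standard deviations and returns velocity times the median
#' inter-peak interval.
#'
#' Broadband surface noise is suppressed before peak picking: the dominant
#' period is scaled off the magnitude spectrum, the trace is smoothed with a
#' moving average of about a sixth of that period, and peaks closer than 60%
#' of a period are merged.
#'
#' @param slide_trace Numeric sliding trace (volts).
#' @param velocity Sliding velocity in cm/s.
#' @param sample_rate Samples per second (default 1000).
#' @param k Peak threshold in trace standard deviations (default 1).
#' @return Estimated pitch in micrometres.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' estimate_pitch(sin(2 * pi * 100 * t), velocity = 4)
estimate_pitch <- function(slide_trace, velocity, sample_rate = 1000, k = 1) {
  check_number(velocity, "velocity", min = 0, strict = TRUE)
  x <- slide_trace - mean(slide_trace)
  # period scale from the dominant spectral component (ties: lowest frequency)
  n <- length(x)
  mag <- Mod(fft(x))[2:max(2, floor(n / 2))]
  f0 <- which.max(mag) * sample_rate / n
  period <- max(2, sample_rate / f0)
  w <- round(period / 6)
  if (w %% 2 == 0) w <- w - 1
  xs <- smooth_ma(x, max(1, w))
  peaks <- find_signal_peaks(xs, k = k, min_dist = round(0.6 * period))
  if (length(peaks) < 2L) {
    abort_estimation("fewer than 2 peaks detected; cannot estimate pitch")
  }
  interval <- stats::median(diff(peaks)) / sample_rate
  velocity * 1e4 * interval # cm/s * s -> cm -> um
}

#' Magnitude spectrum of a sliding signal on integer frequencies 1-500 Hz
#'
#' Removes the trace mean, takes the discrete Fourier transform over the full
#' window, linearly interpolates the magnitude onto integer frequencies
#' 1..500 Hz, and max-normalizes (all-zero traces return all zeros). This is
#' the 500-wide network input encoding surface topography.
#'
#' @param slide_trace Numeric sliding trace; at least 10 samples.
#' @param sample_rate Samples per second; must be 1000 so that 500 Hz is the
#'   Nyquist frequency.
#' @return Numeric vector of length 500, entries in `[0, 1]`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' spec <- slide_spectrum(sin(2 * pi * 100 * t))
#' which.max(spec)
slide_spectrum <- function(slide_trace, sample_rate = 1000) {
  if (sample_rate != 1000) {
    abort_invalid("`sample_rate` must be 1000 (spectrum covers 1-500 Hz)")
  }
  n <- length(slide_trace)
  if (n < 10L) abort_invalid("`slide_trace` shorter than one analysis window")
  x <- slide_trace - mean(slide_trace)
  mag <- Mod(fft(x))[seq_len(floor(n / 2) + 1)]
  freq <- (seq_along(mag) - 1) * sample_rate / n
  out <- approx(freq, mag, xout = 1:500, rule = 2)$y
  m <- max(out)
  if (m > 0) out / m else out
}

#' Extract the 400-sample touch window
#'
#' The network's touch input: exactly 400 samples (400 ms at 1000 samples/s)
#' starting at the contact onset.
#'
#' @param touch_trace Numeric touch trace.
#' @param onset Optional onset index; detected with [detect_onset()] if `NULL`.
#' @param n Window length in samples (default 400).
#' @return Numeric vector of length `n`.
#' @export
touch_window <- function(touch_trace, onset = NULL, n = 400) {
  onset <- onset %||% detect_onset(touch_trace)
  if (onset + n - 1 > length(touch_trace)) {
    abort_invalid(sprintf(
      "touch trace has fewer than %d samples after onset %d", n, onset
    ))
  }
  touch_trace[onset:(onset + n - 1)]
}

#' Preprocess a recording into network inputs
#'
#' Converts one recording (aggregated touch and slide traces) into the
#' feature pair the network consumes: the 400-sample touch window and the
#' 500-bin sliding magnitude spectrum.
#'
#' @param touch Numeric touch trace.
#' @param slide Numeric sliding trace.
#' @param sample_rate Samples per second (default 1000).
#' @return A list with elements `touch_window` (length 400) and
#'   `slide_spectrum` (length 500).
#' @export
preprocess_recording <- function(touch, slide, sample_rate = 1000) {
  list(
    touch_window = touch_window(touch),
    slide_spectrum = slide_spectrum(slide, sample_rate)
  )
}

#' Feature matrices for a whole corpus
#'
#' Applies [preprocess_recording()] to every recording of a corpus tibble and
#' stacks the results into the matrices the network trains on.
#'
#' @param corpus A corpus tibble from [record_corpus()].
#' @return A list with `touch` (n x 400 matrix), `slide` (n x 500 matrix),
#'   `material_id` and `trial` (integer vectors).
#' @export
corpus_features <- function(corpus) {
  if (!is.data.frame(corpus) || nrow(corpus) == 0L) {
    abort_invalid("`corpus` must be a nonempty corpus tibble")
  }
  feats <- purrr::map2(corpus$touch, corpus$slide, preprocess_recording)
  list(
    touch = do.call(rbind, purrr::map(feats, "touch_window")),
    slide = do.call(rbind, purrr::map(feats, "slide_spectrum")),
    material_id = corpus$material_id,
    trial = corpus$trial
  )
}

#' Per-recording scalar feature table
#'
#' Tidy per-trial summary used for signal-level analyses: hardness-coded
#' touch slope and the peak-interval pitch estimate.
#'
#' @param corpus A corpus tibble from [record_corpus()].
#' @param velocity Sliding velocity in cm/s (defaults to the corpus config).
#' @return A tibble with columns `material_id`, `trial`, `slope`,
#'   `pitch_estimate`.
#' @export
feature_table <- function(corpus, velocity = NULL) {
  cfg <- attr(corpus, "config")
  velocity <- velocity %||% (if (!is.null(cfg)) cfg$sliding_velocity else 4)
  sr <- if (!is.null(cfg)) cfg$sample_rate else 1000
  tibble::tibble(
    material_id = corpus$material_id,
    trial = corpus$trial,
    slope = purrr::map_dbl(corpus$touch, function(tr) {
      tryCatch(estimate_touch_slope(tr, sr), error = function(e) NA_real_)
    }),
    pitch_estimate = purrr::map_dbl(corpus$slide, function(tr) {
      tryCatch(estimate_pitch(tr, velocity, sr), error = function(e) NA_real_)
    })
  )
}
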