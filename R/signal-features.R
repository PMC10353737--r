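#' Construct a single-channel EMG trace
#'
#' @param samples Numeric vector of EMG samples (microvolts).
#' @param fs Sampling frequency (Hz).
#' @param muscle Optional muscle label, `"TA"` or `"LG"`.
#' @param side Optional side label, `"left"` or `"right"`.
#' @return An object of class `emg_trace`.
#' @export
emg_trace <- function(samples, fs, muscle = NULL, side = NULL) {
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1, fs > 0)
  if (!all(is.finite(samples))) stop("emg_trace samples must be finite")
  if (!is.null(muscle)) muscle <- match.arg(muscle, c("TA", "LG"))
  if (!is.null(side)) side <- match.arg(side, c("left", "right"))
  structure(list(samples = as.numeric(samples), fs = fs,
                 muscle = muscle, side = side),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %s %s: %d samples @ %g Hz (%.2f s)\n",
              x$muscle %||% "?", x$side %||% "?",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Heel-strike events defining gait cycles
#'
#' A gait cycle runs from one heel strike to the next ipsilateral heel
#' strike.  Times are in seconds from the start of the recording and must be
#' strictly increasing, with at least two strikes per side.
#'
#' @param left,right Numeric vectors of heel-strike times (s).
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(left, right) {
  for (v in list(left, right)) {
    stopifnot(is.numeric(v), length(v) >= 2, all(is.finite(v)))
    if (any(diff(v) <= 0)) stop("heel-strike times must be strictly increasing")
  }
  structure(list(left = as.numeric(left), right = as.numeric(right)),
            class = "gait_events")
}

#' Zero-phase band-pass filter for raw EMG
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the filter is zero-phase: activation timing,
#' an endpoint of the analysis, is not biased by phase delay.  If `high`
#' reaches the Nyquist frequency only the high-pass section at `low` is
#' applied.
#'
#' @param trace An [emg_trace()].
#' @param low,high Band edges in Hz (default 20–500, the conventional
#'   surface-EMG band).
#' @return The filtered [emg_trace()] (same length, same `fs`).
#' @export
bandpass <- function(trace, low = 20, high = 500) {
  stopifnot(inherits(trace, "emg_trace"), low > 0, high > low)
  fs <- trace$fs
  if (fs <= 2 * low)
    stop("sampling rate ", fs, " Hz is unusable for a ", low, " Hz high-pass")
  nyq <- fs / 2
  flt <- if (high >= nyq) signal::butter(4, low / nyq, type = "high")
         else signal::butter(4, c(low, high) / nyq, type = "pass")
  out <- trace
  out$samples <- as.numeric(signal::filtfilt(flt, trace$samples))
  out
}

#' Cut a trace into complete gait cycles
#'
#' Cycle k spans the half-open interval `[strike_k, strike_{k+1})`; a sample
#' at time t (0-based index / fs) belongs to the cycle containing t.  The
#' first `n_keep` complete cycles are retained; fewer than `n_keep` complete
#' cycles is an insufficient-data error naming the channel.
#'
#' @param trace An [emg_trace()].
#' @param events A [gait_events()].
#' @param side `"left"` or `"right"`; defaults to the trace's own side.
#' @param n_keep Number of cycles to retain (default 6).
#' @return List of cycles; each has `samples`, `start` (s) and `duration` (s).
#' @export
segment_cycles <- function(trace, events, side = trace$side, n_keep = 6) {
  stopifnot(inherits(trace, "emg_trace"), inherits(events, "gait_events"))
  side <- match.arg(side, c("left", "right"))
  strikes <- events[[side]]
  label <- paste0(trace$muscle %||% "channel", " ", side)
  n_cycles <- length(strikes) - 1
  if (n_cycles < n_keep)
    stop_insufficient(label, ": only ", n_cycles,
                      " complete gait cycles, need ", n_keep)
  fs <- trace$fs
  n <- length(trace$samples)
  lapply(seq_len(n_keep), function(k) {
    i0 <- ceiling(strikes[k] * fs - 1e-9)        # first sample with t >= strike
    i1 <- ceiling(strikes[k + 1] * fs - 1e-9) - 1
    if (i1 >= n)
      stop_insufficient(label, ": cycle ", k, " extends beyond the recording")
    list(samples = trace$samples[(i0 + 1):(i1 + 1)],
         start = strikes[k],
         duration = strikes[k + 1] - strikes[k])
  })
}

#' Windowed RMS envelope
#'
#' Root-mean-square amplitude in sliding windows (default 30 ms window,
#' 20 ms step).  Windows start at the beginning of the segment; the last
#' window that fits entirely is the final one; each RMS value is stamped
#' with its window-center time (s, relative to the start of the segment).
#'
#' @param x Numeric vector of samples (one gait cycle).
#' @param fs Sampling frequency (Hz).
#' @param window_ms,step_ms Window length and step (milliseconds).
#' @return `data.frame(time, rms)`.
#' @export
#' @examples
#' rms_envelope(sin(2 * pi * 100 * (0:1999) / 2000), fs = 2000)
rms_envelope <- function(x, fs, window_ms = 30, step_ms = 20) {
  stopifnot(is.numeric(x), fs > 0, window_ms > 0, step_ms > 0)
  w <- round(window_ms / 1000 * fs)
  s <- round(step_ms / 1000 * fs)
  if (length(x) < w)
    stop_insufficient("segment of ", length(x),
                      " samples is shorter than one ", window_ms, " ms window")
  nw <- floor((length(x) - w) / s) + 1
  starts <- (seq_len(nw) - 1) * s
  cs <- c(0, cumsum(x^2))
  rms <- sqrt((cs[starts + w + 1] - cs[starts + 1]) / w)
  data.frame(time = (starts + (w - 1) / 2) / fs, rms = rms)
}

#' Map an RMS envelope onto the normalized gait-cycle grid
#'
#' Window-center times are expressed as percent of the gait cycle and
#' linearly interpolated onto the fixed 0, 1, ..., 100 % grid (101 points);
#' positions outside the sampled range are held at the nearest computed
#' value.
#'
#' @param times Window-center times (s).
#' @param values RMS values at `times`.
#' @param cycle_start Cycle start time (s) on the same clock as `times`.
#' @param cycle_duration Cycle duration (s).
#' @return A `cycle_envelope`: numeric vector of length 101.
#' @export
normalize_envelope <- function(times, values, cycle_start, cycle_duration) {
  stopifnot(length(times) == length(values), cycle_duration > 0)
  if (length(times) < 2)
    stop_insufficient("need at least 2 RMS windows to normalize an envelope")
  pct <- (times - cycle_start) / cycle_duration * 100
  env <- approx(pct, values, xout = 0:100, rule = 2, ties = "ordered")$y
  structure(env, class = "cycle_envelope")
}

#' Average envelope over the six analysed gait cycles
#'
#' @param envelopes List of exactly six `cycle_envelope`s (cycle selection
#'   happens upstream in [segment_cycles()]).
#' @return Pointwise-mean `cycle_envelope`.
#' @export
mean_envelope <- function(envelopes) {
  if (length(envelopes) != 6)
    stop("mean_envelope expects exactly 6 cycle envelopes, got ",
         length(envelopes))
  stopifnot(all(vapply(envelopes, length, 1L) == 101))
  structure(rowMeans(do.call(cbind, envelopes)), class = "cycle_envelope")
}

#' RMS peak and RMS peak time of an averaged envelope
#'
#' The peak is the maximum of the 101-point envelope; the peak time is its
#' position in percent of the gait cycle (first occurrence on ties).
#'
#' @param env A `cycle_envelope`.
#' @return List with `rms_peak` (microvolts) and `rms_peak_time` (percent).
#' @export
peak_features <- function(env) {
  stopifnot(length(env) == 101, all(env >= 0))
  i <- which.max(env)
  list(rms_peak = as.numeric(env[i]), rms_peak_time = as.numeric(i - 1))
}

#' Mean and median power frequency of one gait cycle
#'
#' One-sided periodogram (Hann taper, whole cycle, no sub-windowing)
#' restricted to the analysis band.  MPF is the power-weighted mean
#' frequency; MF is the frequency at which cumulative band power reaches
#' half the total, linearly interpolated between frequency bins.
#'
#' @param x Numeric vector of samples (one gait cycle, at least 0.25 s).
#' @param fs Sampling frequency (Hz).
#' @param band Analysis band (Hz), default `c(20, 500)`.
#' @return List with `mpf` and `mf` (Hz).
#' @export
#' @examples
#' t <- (0:2199) / 2000
#' spectral_features(sin(2 * pi * 100 * t), fs = 2000)
spectral_features <- function(x, fs, band = c(20, 500)) {
  stopifnot(is.numeric(x), fs > 0, length(band) == 2, band[1] < band[2])
  if (length(x) < 0.25 * fs)
    stop_insufficient("cycle of ", length(x), " samples is shorter than 0.25 s")
  if (all(x == 0)) stop("undefined spectrum: all-zero signal")
  n <- length(x)
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- fft(x * taper)
  nh <- floor(n / 2)
  f <- (1:nh) * fs / n
  p <- Mod(X[2:(nh + 1)])^2
  keep <- f >= band[1] & f <= min(band[2], fs / 2)
  f <- f[keep]; p <- p[keep]
  if (sum(p) <= 0) stop("undefined spectrum: no power in the analysis band")
  mpf <- sum(f * p) / sum(p)
  cum <- cumsum(p)
  half <- sum(p) / 2
  mf <- if (half <= cum[1]) f[1]
        else approx(cum, f, xout = half, ties = "ordered")$y
  list(mpf = mpf, mf = mf)
}

#' Average spectral features over the six analysed gait cycles
#'
#' MPF and MF are computed per cycle with [spectral_features()] and
#' arithmetically averaged.
#'
#' @param cycles List of exactly six cycles as returned by
#'   [segment_cycles()] (or plain sample vectors).
#' @param fs Sampling frequency (Hz).
#' @param band Analysis band (Hz).
#' @return List with `mpf` and `mf` (Hz), averaged over cycles.
#' @export
per_cycle_spectral_mean <- function(cycles, fs, band = c(20, 500)) {
  if (length(cycles) != 6)
    stop("per_cycle_spectral_mean expects exactly 6 cycles, got ",
         length(cycles))
  vals <- lapply(seq_along(cycles), function(k) {
    x <- if (is.list(cycles[[k]])) cycles[[k]]$samples else cycles[[k]]
    tryCatch(spectral_features(x, fs, band),
             error = function(e) stop("cycle ", k, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  list(mpf = mean(vapply(vals, `[[`, 1, "mpf")),
       mf = mean(vapply(vals, `[[`, 1, "mf")))
}

#' Extract the four SEMG parameters for every channel of a recording
#'
#' Runs the full per-channel chain: band-pass filter, segmentation into the
#' first six complete gait cycles, windowed RMS envelope per cycle,
#' normalization to the 0–100 % grid, envelope averaging, peak extraction
#' (RMS peak, RMS peak time), and per-cycle spectral features averaged over
#' cycles (MPF, MF).
#'
#' @param rec A `raw_recording` (see [simulate_subject()] /
#'   [read_recording()]).
#' @param low,high Band-pass edges (Hz).
#' @return A `subject_record`: list with `id`, `group`, `symptomatic_side`
#'   and `features`, a data.frame with one row per muscle/side and columns
#'   `muscle`, `side`, `rms_peak`, `rms_peak_time`, `mpf`, `mf`.
#' @export
extract_subject <- function(rec, low = 20, high = 500) {
  stopifnot(inherits(rec, "raw_recording"))
  rows <- list(); failures <- character()
  for (nm in names(rec$traces)) {
    res <- tryCatch({
      tr <- rec$traces[[nm]]
      bp <- bandpass(tr, low, high)
      cycles <- segment_cycles(bp, rec$events, tr$side)
      envs <- lapply(cycles, function(cy) {
        e <- rms_envelope(cy$samples, bp$fs)
        normalize_envelope(e$time, e$rms, 0, cy$duration)
      })
      pk <- peak_features(mean_envelope(envs))
      sp <- per_cycle_spectral_mean(cycles, bp$fs, band = c(low, high))
      data.frame(muscle = tr$muscle, side = tr$side,
                 rms_peak = pk$rms_peak, rms_peak_time = pk$rms_peak_time,
                 mpf = sp$mpf, mf = sp$mf, stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[nm] <- res else rows[[nm]] <- res
  }
  if (length(failures))
    stop("extraction failed for subject ", rec$id %||% "?", " — ",
         paste0(names(failures), ": ", failures, collapse = "; "))
  structure(list(id = rec$id %||% NA_character_,
                 group = rec$group,
                 symptomatic_side = rec$symptomatic_side,
                 features = do.call(rbind, c(rows, make.row.names = FALSE)),
                 metadata = rec$metadata %||% list()),
            class = "subject_record")
}
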