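#' Band-shaped stochastic carrier signal
#'
#' Generates zero-mean noise whose one-sided power spectral density follows
#' the parametric EMG spectrum of [emg_spectrum()], by frequency-domain
#' amplitude shaping: deterministic amplitudes \eqn{\sqrt{P(f_k)}} with
#' independent uniform random phases, inverse FFT, then scaling to exactly
#' unit RMS.  The DC bin is zeroed, so the sample mean is exactly zero.
#'
#' @param duration Signal duration (s), > 0.
#' @param fs Sampling frequency (Hz); must be at least `2 * f_high`.
#' @param spectrum An [emg_spectrum()].
#' @param seed Optional integer seed; the same seed and arguments yield an
#'   identical trace, and the caller's RNG state is left untouched.
#' @return An [emg_trace()] with unit RMS.
#' @export
#' @examples
#' tr <- shaped_noise(1, 2000, emg_spectrum(40, 90), seed = 1)
#' sqrt(mean(tr$samples^2))
shaped_noise <- function(duration, fs, spectrum, seed = NULL) {
  stopifnot(inherits(spectrum, "emg_spectrum"), duration > 0, fs > 0)
  if (fs < 2 * spectrum$f_high)
    stop("sampling rate ", fs, " Hz too low for f_high = ",
         spectrum$f_high, " Hz (need fs >= 2*f_high)")
  n <- round(duration * fs)
  if (n < 4) stop("duration too short at this sampling rate")
  with_seed(seed, {
    nh <- floor((n - 1) / 2)                 # strictly positive, non-Nyquist bins
    f <- (1:nh) * fs / n
    amp <- sqrt(emg_psd(f, spectrum))
    phase <- runif(nh, 0, 2 * pi)
    X <- complex(length.out = n)             # X[1] (DC) stays 0
    X[2:(nh + 1)] <- amp * exp(1i * phase)
    X[n:(n - nh + 1)] <- Conj(X[2:(nh + 1)])
    if (n %% 2 == 0) {                       # real Nyquist bin, random sign
      fn <- fs / 2
      X[nh + 2] <- sqrt(emg_psd(fn, spectrum)) * sample(c(-1, 1), 1)
    }
    x <- Re(fft(X, inverse = TRUE)) / n
    x <- x / sqrt(mean(x^2))
    emg_trace(x, fs)
  })
}

#' Specify one Gaussian activation burst
#'
#' Activation envelopes are modeled as sums of Gaussian bursts positioned in
#' percent of the gait cycle; `amplitude` is the target windowed-RMS value at
#' the burst peak.
#'
#' @param amplitude Peak RMS amplitude (microvolts), >= 0.
#' @param center Burst center (% of gait cycle, 0–100).
#' @param width Burst standard deviation (% of gait cycle), > 0.
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(amplitude, center, width) {
  stopifnot(amplitude >= 0, center >= 0, center <= 100, width > 0)
  structure(list(amplitude = amplitude, center = center, width = width),
            class = "burst_spec")
}

#' Simulation profile for one muscle on one side
#'
#' @param bursts A `burst_spec` or list of them (at least one).
#' @param spectrum An [emg_spectrum()] carrier spectrum; its expected MPF
#'   must lie in the 20–500 Hz analysis band.
#' @return An object of class `muscle_sim_profile`.
#' @export
muscle_sim_profile <- function(bursts, spectrum) {
  if (inherits(bursts, "burst_spec")) bursts <- list(bursts)
  stopifnot(length(bursts) >= 1,
            all(vapply(bursts, inherits, TRUE, "burst_spec")),
            inherits(spectrum, "emg_spectrum"))
  mpf <- spectral_moments(spectrum, band = c(0.5, 500))$mpf
  if (mpf < 20 || mpf > 500)
    stop("carrier spectrum has expected MPF ", round(mpf, 1),
         " Hz outside [20, 500]")
  structure(list(bursts = bursts, spectrum = spectrum),
            class = "muscle_sim_profile")
}

#' Subject-level simulation profile
#'
#' Bundles the four per-muscle/per-side profiles with gait timing.  Healthy
#' subjects have no symptomatic side; patients have exactly one.
#'
#' @param group `"healthy"`, `"L5"` or `"S1"`.
#' @param symptomatic_side `"left"`, `"right"` or `"none"` (healthy only).
#' @param muscles Named list with elements `TA_left`, `TA_right`, `LG_left`,
#'   `LG_right`, each a [muscle_sim_profile()].
#' @param cycle_duration_mean Mean gait-cycle duration (s).
#' @param cycle_duration_jitter_sd SD of cycle-duration jitter (s).
#' @param n_cycles Number of gait cycles to simulate per side (>= 6).
#' @return An object of class `subject_sim_profile`.
#' @export
subject_sim_profile <- function(group, symptomatic_side, muscles,
                                cycle_duration_mean = 1.1,
                                cycle_duration_jitter_sd = 0.05,
                                n_cycles = 8) {
  group <- match.arg(group, semg_classes())
  symptomatic_side <- match.arg(symptomatic_side, c("left", "right", "none"))
  if ((group == "healthy") != (symptomatic_side == "none"))
    stop("healthy subjects must have symptomatic_side = \"none\" and patients a real side")
  need <- c("TA_left", "TA_right", "LG_left", "LG_right")
  stopifnot(all(need %in% names(muscles)),
            all(vapply(muscles[need], inherits, TRUE, "muscle_sim_profile")),
            cycle_duration_mean > 0, cycle_duration_jitter_sd >= 0,
            n_cycles >= 6)
  structure(list(group = group, symptomatic_side = symptomatic_side,
                 muscles = muscles[need],
                 cycle_duration_mean = cycle_duration_mean,
                 cycle_duration_jitter_sd = cycle_duration_jitter_sd,
                 n_cycles = n_cycles),
            class = "subject_sim_profile")
}

# Calibration constants for the default class-conditional profiles.
# Activation centers, widths and peak amplitudes follow the published
# per-side cohort medians (healthy values from the three-group comparison
# table; patient values from the symptomatic/asymptomatic tables); spectrum
# corners were fitted with fit_spectrum() so the band-limited MPF/MF of the
# carrier match the corresponding cohort MPF/MF cells.
# S1 gastrocnemius on the symptomatic side gets a second, smaller burst at
# the normal late-stance position: the early compensatory peak dominates,
# giving the bimodal pattern seen in S1 patients.
.sim_calibration <- list(
  healthy = list(
    TA_symp = list(amp = 45.31, center = 5.25, width = 4, fl = 40.7, fh = 49.9),
    TA_asym = list(amp = 45.31, center = 5.25, width = 4, fl = 40.7, fh = 49.9),
    LG_symp = list(amp = 30.99, center = 38.75, width = 6, fl = 36.7, fh = 45.7),
    LG_asym = list(amp = 30.99, center = 38.75, width = 6, fl = 36.7, fh = 45.7)),
  L5 = list(
    TA_symp = list(amp = 48.89, center = 35, width = 8, fl = 46.3, fh = 46.6),
    TA_asym = list(amp = 34.16, center = 11, width = 4, fl = 67.0, fh = 67.4),
    LG_symp = list(amp = 24.99, center = 43, width = 6, fl = 65.3, fh = 65.7),
    LG_asym = list(amp = 30.12, center = 43, width = 6, fl = 2.0, fh = 129.7)),
  S1 = list(
    TA_symp = list(amp = 39.63, center = 6, width = 4, fl = 50.3, fh = 50.7),
    TA_asym = list(amp = 62.49, center = 5, width = 4, fl = 2.0, fh = 108.8),
    LG_symp = list(amp = 45.10, center = 27, width = 5, fl = 23.5, fh = 70.4,
                   amp2 = 31.5, center2 = 44, width2 = 5),
    LG_asym = list(amp = 62.28, center = 44, width = 5, fl = 77.7, fh = 78.0)))

#' Default class-conditional subject profile
#'
#' Builds a [subject_sim_profile()] calibrated so that extracted features
#' reproduce the published per-side cohort medians: healthy subjects show an
#' early TA burst (~5 % of the cycle) and a late-stance LG burst (~39 %);
#' L5 compression delays the symptomatic TA burst to ~35 % and lowers TA
#' MPF/MF; S1 compression advances the symptomatic LG activation to ~27 %
#' with a smaller residual late-stance burst (bimodal pattern) and lowers LG
#' MPF/MF.  Symptomatic-side spectral slowing is realized by lowering the
#' carrier's corner frequencies.
#'
#' @param group `"healthy"`, `"L5"` or `"S1"`.
#' @param symptomatic_side `"left"` or `"right"` for patients; forced to
#'   `"none"` for healthy subjects.
#' @param n_cycles Gait cycles to simulate (default 8).
#' @inheritParams subject_sim_profile
#' @return A [subject_sim_profile()].
#' @export
#' @examples
#' prof <- default_subject_profile("L5")
#' prof$muscles$TA_left$bursts[[1]]$center   # delayed symptomatic TA burst
default_subject_profile <- function(group = c("healthy", "L5", "S1"),
                                    symptomatic_side = "left",
                                    cycle_duration_mean = 1.1,
                                    cycle_duration_jitter_sd = 0.05,
                                    n_cycles = 8) {
  group <- match.arg(group)
  if (group == "healthy") symptomatic_side <- "none"
  cal <- .sim_calibration[[group]]
  mk <- function(p) {
    bursts <- list(burst_spec(p$amp, p$center, p$width))
    if (!is.null(p$amp2))
      bursts <- c(bursts, list(burst_spec(p$amp2, p$center2, p$width2)))
    muscle_sim_profile(bursts, emg_spectrum(p$fl, p$fh))
  }
  symp <- if (symptomatic_side == "right") "right" else "left"
  muscles <- list()
  for (m in c("TA", "LG")) {
    muscles[[paste0(m, "_", symp)]] <- mk(cal[[paste0(m, "_symp")]])
    other <- setdiff(c("left", "right"), symp)
    muscles[[paste0(m, "_", other)]] <- mk(cal[[paste0(m, "_asym")]])
  }
  subject_sim_profile(group, symptomatic_side, muscles,
                      cycle_duration_mean, cycle_duration_jitter_sd, n_cycles)
}

#' Render a muscle's EMG over a sequence of gait cycles
#'
#' For each cycle the Gaussian-burst envelope (positioned in percent of that
#' cycle) multiplies a unit-RMS shaped-noise carrier, and the cycles are
#' concatenated.  Because the carrier has unit RMS, the windowed-RMS peak of
#' a rendered burst equals the burst amplitude in expectation (within ~10 %).
#'
#' @param profile A [muscle_sim_profile()].
#' @param cycle_durations Positive cycle durations (s), at least one.
#' @param fs Sampling frequency (Hz).
#' @param seed Optional seed (deterministic output for fixed arguments).
#' @return An [emg_trace()] spanning all cycles.
#' @export
render_cycles <- function(profile, cycle_durations, fs, seed = NULL) {
  stopifnot(inherits(profile, "muscle_sim_profile"))
  if (length(cycle_durations) == 0) stop("cycle_durations must be non-empty")
  if (any(cycle_durations <= 0)) stop("cycle durations must be positive")
  with_seed(seed, {
    segs <- lapply(cycle_durations, function(d) {
      n <- round(d * fs)
      pct <- (seq_len(n) - 1) / n * 100
      env <- 0
      for (b in profile$bursts)
        env <- env + b$amplitude * exp(-0.5 * ((pct - b$center) / b$width)^2)
      if (all(env == 0)) return(numeric(n))
      carrier <- shaped_noise(n / fs, fs, profile$spectrum)
      env * carrier$samples
    })
    emg_trace(unlist(segs), fs)
  })
}

#' Simulate a complete four-channel walking-EMG recording
#'
#' Draws jittered cycle durations (rounded to the sample grid), places heel
#' strikes for the left side and, offset by half a cycle, for the right
#' side, renders each of the four muscle-side channels with
#' [render_cycles()], and assembles traces plus events.  Each side has
#' `n_cycles + 1` heel strikes, i.e. at least 6 complete cycles.
#'
#' @param profile A [subject_sim_profile()] (e.g.
#'   [default_subject_profile()]).
#' @param seed Optional master seed for this subject; channel carriers use
#'   derived sub-streams.
#' @param fs Sampling frequency (Hz), default 2000.
#' @param id Optional subject identifier carried into the output.
#' @return A `raw_recording`: list with `traces` (named `TA_left`,
#'   `TA_right`, `LG_left`, `LG_right`), `events` ([gait_events()]), `group`,
#'   `symptomatic_side`, `id`.
#' @export
#' @examples
#' rec <- simulate_subject(default_subject_profile("healthy"), seed = 1)
#' extract_subject(rec)$features
simulate_subject <- function(profile, seed = NULL, fs = 2000, id = NULL) {
  stopifnot(inherits(profile, "subject_sim_profile"))
  with_seed(seed, {
    m <- profile$n_cycles
    dur <- rnorm(m + 1, profile$cycle_duration_mean,
                 profile$cycle_duration_jitter_sd)
    dur <- pmax(dur, 0.5 * profile$cycle_duration_mean)
    nsamp <- round(dur * fs)
    t0 <- round(0.25 * fs)
    left_idx <- t0 + c(0, cumsum(nsamp[1:m]))             # m + 1 strikes
    right_idx <- left_idx + round(nsamp / 2)              # half-cycle offset
    n_total <- max(left_idx[m + 1], right_idx[m + 1]) + round(0.25 * fs)
    sides <- list(left = left_idx, right = right_idx)
    traces <- list()
    ch <- 0
    for (muscle in c("TA", "LG")) for (side in c("left", "right")) {
      ch <- ch + 1
      idx <- sides[[side]]
      seg_n <- diff(idx)
      rendered <- render_cycles(profile$muscles[[paste0(muscle, "_", side)]],
                                seg_n / fs, fs)
      x <- numeric(n_total)
      x[(idx[1] + 1):(idx[1] + length(rendered$samples))] <- rendered$samples
      traces[[paste0(muscle, "_", side)]] <- emg_trace(x, fs, muscle, side)
    }
    structure(list(traces = traces,
                   events = gait_events(left_idx / fs, right_idx / fs),
                   group = profile$group,
                   symptomatic_side = profile$symptomatic_side,
                   id = id),
              class = "raw_recording")
  })
}

#' Log-normal parameters from a printed median and quartiles
#'
#' Summary tables report skewed features as median (q1, q3).  A log-normal
#' law with location `ln(median)` and scale
#' `(ln q3 - ln q1) / (2 * qnorm(0.75))` has exactly the requested median
#' and approximately the requested interquartile range, and is the
#' generative law used for feature-level cohort sampling.
#'
#' @param median,q1,q3 Positive summary values with `q1 <= median <= q3`.
#' @return List with `location` and `scale` (log scale), class
#'   `lognormal_params`.
#' @export
#' @examples
#' lognormal_from_median_iqr(26, 14, 44.5)
lognormal_from_median_iqr <- function(median, q1, q3) {
  stopifnot(is.numeric(median), is.numeric(q1), is.numeric(q3))
  if (!(q1 > 0 && q1 <= median && median <= q3))
    stop("need 0 < q1 <= median <= q3 (log-normal fit is on the log scale)")
  structure(list(location = log(median),
                 scale = (log(q3) - log(q1)) / (2 * qnorm(0.75))),
            class = "lognormal_params")
}

#' Reference class-conditional distributions of the difference features
#'
#' Published medians and quartiles of the eight absolute bilateral-difference
#' features for the three diagnostic classes (29 L5, 29 S1, 30 healthy
#' subjects).  These summaries calibrate [sample_feature_cohort()].  One
#' healthy quartile is printed as 0 (TA RMS-peak time, values rounded to
#' integer percent); it is stored as 0.5 — half the printed resolution — so
#' the log-scale fit is defined.
#'
#' @return `data.frame` with columns `class`, `feature`, `median`, `q1`,
#'   `q3` (24 rows).
#' @export
diff_feature_reference <- function() {
  ref <- rbind(
    data.frame(class = "L5", feature = diff_feature_names(),
               median = c(13.19, 26, 15.42, 10.91, 9.93, 20, 25.09, 27.21),
               q1 = c(6.28, 14, 5.41, 6.26, 4.50, 3, 4.78, 9.27),
               q3 = c(22.84, 44.5, 28.89, 32.24, 16.68, 34.5, 56.82, 58.21)),
    data.frame(class = "S1", feature = diff_feature_names(),
               median = c(21.90, 1, 12.02, 9.71, 12.83, 29.69, 23.21, 18),
               q1 = c(17.57, 0.5, 5.78, 3.92, 4.34, 15.34, 16.73, 10),
               q3 = c(30.59, 4, 20.75, 17.65, 31.31, 51.22, 46.32, 29)),
    data.frame(class = "healthy", feature = diff_feature_names(),
               median = c(8.06, 1, 11.97, 13.0, 5.16, 1.5, 7.85, 13.26),
               q1 = c(4.43, 0.5, 5.58, 7.08, 1.84, 1, 3.86, 10.17),
               q3 = c(11.33, 4, 29.91, 25.80, 9.28, 31.25, 11.35, 31.14)))
  rownames(ref) <- NULL
  ref
}

#' Sample a labeled feature-level cohort
#'
#' Draws classifier-ready eight-feature vectors: every feature of every
#' subject is an independent draw from the class-conditional log-normal law
#' fitted to the reference median/quartiles
#' ([lognormal_from_median_iqr()]).  Only per-feature marginals are
#' published, so features are sampled independently within class.
#'
#' @param n_per_class Named counts, e.g. `c(healthy = 30, L5 = 29, S1 = 29)`
#'   (the study's cohort sizes); zeros allowed.
#' @param dist Reference distribution table in the format of
#'   [diff_feature_reference()].
#' @param seed Optional seed; identical calls with the same seed return
#'   identical tables.
#' @return `data.frame` with `subject_id`, `group` (factor with levels
#'   [semg_classes()]) and the eight [diff_feature_names()] columns.
#' @export
#' @examples
#' cohort <- sample_feature_cohort(seed = 1)
#' table(cohort$group)
sample_feature_cohort <- function(n_per_class = c(healthy = 30, L5 = 29, S1 = 29),
                                  dist = diff_feature_reference(),
                                  seed = NULL) {
  classes <- intersect(semg_classes(), names(n_per_class))
  if (length(classes) != 3)
    stop("n_per_class must name all three classes: ",
         paste(semg_classes(), collapse = ", "))
  feats <- diff_feature_names()
  for (cl in classes) for (ft in feats)
    if (!any(dist$class == cl & dist$feature == ft))
      stop("reference distribution missing class ", cl, ", feature ", ft)
  with_seed(seed, {
    blocks <- lapply(classes, function(cl) {
      n <- n_per_class[[cl]]
      stopifnot(n >= 0)
      m <- matrix(NA_real_, nrow = n, ncol = length(feats),
                  dimnames = list(NULL, feats))
      for (ft in feats) {
        row <- dist[dist$class == cl & dist$feature == ft, ][1, ]
        lp <- lognormal_from_median_iqr(row$median, row$q1, row$q3)
        m[, ft] <- rlnorm(n, lp$location, lp$scale)
      }
      df <- data.frame(subject_id = sprintf("%s_%02d", cl, seq_len(n)),
                       group = rep(cl, n), stringsAsFactors = FALSE)
      cbind(df, as.data.frame(m))
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out$group <- factor(out$group, levels = semg_classes())
    out
  })
}
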