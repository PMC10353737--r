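# Independent oracles used across the suite.  Each one recomputes a quantity
# by a different route than the package (explicit loops, enumeration, Monte
# Carlo), so agreement is evidence rather than tautology.

# Naive loop-based windowed RMS.
rms_envelope_loop <- function(x, fs, window_ms = 30, step_ms = 20) {
  w <- round(window_ms / 1000 * fs)
  s <- round(step_ms / 1000 * fs)
  out <- numeric(0); times <- numeric(0)
  start <- 0
  while (start + w <= length(x)) {
    seg <- x[(start + 1):(start + w)]
    out <- c(out, sqrt(mean(seg^2)))
    times <- c(times, (start + (w - 1) / 2) / fs)
    start <- start + s
  }
  data.frame(time = times, rms = out)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
# (requires no zero differences and no tied absolute differences).
signed_rank_p_enum <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (w_obs > mu) 2 * mean(w_all >= w_obs) else 2 * mean(w_all <= w_obs)
  min(1, p)
}

# Kruskal-Wallis H from the textbook rank formula (no ties).
kruskal_h_hand <- function(values, groups) {
  stopifnot(!anyDuplicated(values))
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(idx) * (mean(r[idx]) - (n + 1) / 2)^2
  }
  12 / (n * (n + 1)) * h
}

# Brute-force one-vs-rest AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
auc_pairs <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Monte-Carlo power of the two-sample two-tailed t test.
mc_power <- function(n, d, alpha = 0.05, nsim = 1e5, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(nsim * n, mean = d), n)
  y <- matrix(rnorm(nsim * n), n)
  sp <- sqrt((apply(x, 2, var) + apply(y, 2, var)) / 2)
  tstat <- (colMeans(x) - colMeans(y)) / (sp * sqrt(2 / n))
  mean(abs(tstat) > qt(1 - alpha / 2, 2 * n - 2))
}

# Manually assembled subject record (bypasses extraction) for feature-level
# statistics tests.
make_record <- function(group, symptomatic_side, values, id = "s1") {
  # values: named list muscle_side -> c(rms_peak, rms_peak_time, mpf, mf)
  rows <- lapply(names(values), function(nm) {
    p <- strsplit(nm, "_")[[1]]
    v <- values[[nm]]
    data.frame(muscle = p[1], side = p[2], rms_peak = v[1],
               rms_peak_time = v[2], mpf = v[3], mf = v[4],
               stringsAsFactors = FALSE)
  })
  structure(list(id = id, group = group, symptomatic_side = symptomatic_side,
                 features = do.call(rbind, rows), metadata = list()),
            class = "subject_record")
}

# Run the extraction chain on a rendered trace laid out as identical-duration
# cycles, returning the averaged normalized envelope.
mean_envelope_of <- function(trace, cycle_dur, n_cycles = 6) {
  events <- gait_events(seq(0, by = cycle_dur, length.out = n_cycles + 1),
                        seq(0.01, by = cycle_dur, length.out = n_cycles + 1))
  cycles <- segment_cycles(trace, events, "left", n_keep = n_cycles)
  envs <- lapply(cycles, function(cy) {
    e <- rms_envelope(cy$samples, trace$fs)
    normalize_envelope(e$time, e$rms, 0, cy$duration)
  })
  mean_envelope(envs)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}
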