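# Preprocessing: eye speed, velocity-threshold saccade detection, LFP
# band-limiting/down-sampling, channel normalization, and tau-centered
# epoch extraction on the fixation-aligned time axis (t = 0 = saccade end).

#' A tau-centered analysis window on the fixation-aligned axis
#'
#' A window of even length L centered at `tau` covers the 1 ms samples
#' `tau - L/2, ..., tau + L/2 - 1` (so tau = 0, L = 100 is -50..+49 ms, the
#' peri-saccadic interval; tau = 250 is the post-saccadic fixation 200..299;
#' tau = -250 the pre-saccadic fixation -300..-201).
#'
#' @param tau window center in ms relative to fixation onset.
#' @param length window length in ms (even).
#' @return object of class `window_spec` with fields `tau`, `length`,
#'   `times` (the sample times).
#' @export
window_spec <- function(tau, length = 100) {
  if (length <= 0 || length %% 2 != 0)
    ps_error("window length must be a positive even number of ms",
             "perisacc_invalid_config")
  tau <- as.integer(round(tau))
  structure(list(tau = tau, length = as.integer(length),
                 times = seq(tau - length / 2, tau + length / 2 - 1)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("<window_spec> tau = ", x$tau, " ms, length ", x$length,
      " ms: samples ", x$times[1], "..", x$times[x$length], " ms\n", sep = "")
  invisible(x)
}

#' Eye speed from a 2-component position trace
#'
#' Central differences in the interior, one-sided differences at the
#' endpoints, applied per component; speed is the Euclidean norm of the
#' velocity vector. Output has the same length as the input.
#'
#' @param pos 2 x T (or T-vector for 1-component) eye position in deg.
#' @param sample_rate sampling rate in Hz.
#' @return nonnegative speed trace in deg/s.
#' @export
compute_speed <- function(pos, sample_rate = 1000) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  n <- ncol(pos)
  if (n < 2)
    ps_error("need at least 2 samples to estimate speed",
             "perisacc_insufficient_data")
  dt <- 1 / sample_rate
  vel <- apply(pos, 1, function(x) {
    c(x[2] - x[1],
      if (n > 2) (x[3:n] - x[1:(n - 2)]) / 2 else NULL,
      x[n] - x[n - 1]) / dt
  })
  sqrt(rowSums(vel^2))
}

#' Detect a saccade with the 3-SD velocity criterion
#'
#' The mean and SD of eye speed are computed over a steady-fixation
#' baseline interval. Saccade onset is the first sample whose speed exceeds
#' mean + 3 SD; the end -- which defines fixation onset, t = 0 -- is the
#' first sample after onset whose speed falls back below that threshold.
#'
#' @param speed speed trace in deg/s.
#' @param time sample times in ms (defaults to 0-based indices).
#' @param baseline_idx indices into `speed` used as the fixation baseline;
#'   must precede the saccade and contain >= 2 samples.
#' @param n_sd threshold in baseline SDs (default 3).
#' @param smooth odd width of a moving-average filter applied to the speed
#'   before thresholding (1 = none); default 5 samples.
#' @param threshold explicit speed threshold (deg/s) overriding the
#'   baseline-derived mean + `n_sd` SD.
#' @return list with `onset_ms`, `end_ms`, `threshold`.
#' @export
detect_saccade <- function(speed, time = seq_along(speed) - 1,
                           baseline_idx, n_sd = 3, smooth = 5,
                           threshold = NULL) {
  if (length(baseline_idx) < 2)
    ps_error("baseline needs >= 2 samples", "perisacc_insufficient_data")
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    speed <- stats::filter(speed, k, sides = 2)
    speed[is.na(speed)] <- speed[!is.na(speed)][1]
    speed <- as.numeric(speed)
  }
  bl <- speed[baseline_idx]
  thr <- threshold %||% (mean(bl) + n_sd * stats::sd(bl))
  after <- max(baseline_idx)
  cand <- which(speed > thr & seq_along(speed) > after)
  if (length(cand) == 0)
    ps_error("no sample exceeds the velocity threshold",
             "perisacc_no_saccade")
  # anchor at the speed maximum so brief noise crossings before the
  # saccade do not trigger; onset/end are the threshold crossings of the
  # suprathreshold run containing the peak (identical to the plain
  # first-crossing rule on a clean unimodal pulse)
  peak <- cand[which.max(speed[cand])]
  run_start <- peak
  while (run_start > after + 1 && speed[run_start - 1] > thr)
    run_start <- run_start - 1
  onset <- run_start
  below <- which(speed < thr & seq_along(speed) > peak)
  if (length(below) == 0)
    ps_error("speed never falls back below the velocity threshold",
             "perisacc_unterminated_saccade")
  list(onset_ms = time[onset], end_ms = time[below[1]], threshold = thr)
}

#' Detect saccade events for every trial of a trial set
#'
#' Runs [compute_speed()] and [detect_saccade()] on each trial's eye trace,
#' using the pre-saccadic fixation period as the velocity baseline, and
#' returns an events table on the trial time axis.
#'
#' @param trials a `trial_set`.
#' @param baseline_ms ms interval (on the trial axis) of steady fixation
#'   used for the velocity baseline.
#' @param ... passed to [detect_saccade()].
#' @return data.frame (trial_id, onset_ms, end_ms, direction_deg).
#' @export
detect_events <- function(trials, baseline_ms = c(-300, -150), ...) {
  tm <- trials$time
  bidx <- which(tm >= baseline_ms[1] & tm <= baseline_ms[2])
  out <- lapply(seq_len(dim(trials$eye)[1]), function(k) {
    sp <- compute_speed(trials$eye[k, , ], trials$sample_rate_eye)
    det <- detect_saccade(sp, tm, bidx, ...)
    data.frame(trial_id = k, onset_ms = det$onset_ms, end_ms = det$end_ms,
               direction_deg = trials$events$direction_deg[k])
  })
  do.call(rbind, out)
}

#' Low-pass filter and down-sample a raw trace
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass at
#' `cutoff`, then decimation by the integer factor `rate_in / rate_out`.
#' The emulated recording chain low-passes at 300 Hz before sampling the
#' 30 kHz raw signal at 1 kHz. No relation between `cutoff` and the output
#' Nyquist frequency is enforced: with the default 300 Hz cutoff and 1 kHz
#' output, energy between the cutoff and 500 Hz is attenuated only by the
#' filter roll-off, so some aliasing of that band is possible by design.
#'
#' @param raw numeric trace sampled at `rate_in`.
#' @param rate_in input rate, Hz.
#' @param rate_out output rate, Hz; must divide `rate_in`.
#' @param cutoff low-pass cutoff, Hz.
#' @param order Butterworth order (per pass).
#' @return down-sampled trace of length `length(raw) * rate_out / rate_in`.
#' @export
lowpass_downsample <- function(raw, rate_in = 30000, rate_out = 1000,
                               cutoff = 300, order = 4) {
  if (rate_in %% rate_out != 0)
    ps_error("rate_in must be an integer multiple of rate_out",
             "perisacc_unsupported_rate")
  bf <- signal::butter(order, cutoff / (rate_in / 2), type = "low")
  # reflect-pad to suppress filtfilt edge transients
  n <- length(raw)
  np <- min(n - 1, 3 * ceiling(rate_in / cutoff))
  padded <- c(2 * raw[1] - raw[(np + 1):2],
              raw,
              2 * raw[n] - raw[(n - 1):(n - np)])
  filt <- signal::filtfilt(bf, padded)[(np + 1):(np + n)]
  filt[seq(1, n, by = rate_in / rate_out)]
}

#' Fit per-channel normalization statistics
#'
#' Pools the channel's LFP across all trials and time to compute a mean
#' and a population SD (divide by n). Flat channels are rejected as dead.
#'
#' @param trials a `trial_set`.
#' @param channel channel index.
#' @return list(mean, sd) of class `norm_stats`.
#' @export
fit_norm_stats <- function(trials, channel) {
  x <- as.numeric(trials$lfp[, channel, ])
  if (length(x) < 2)
    ps_error("need >= 2 pooled samples", "perisacc_insufficient_data")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0)
    ps_error(sprintf("channel %d is flat (zero SD); excluded", channel),
             "perisacc_dead_channel")
  structure(list(mean = m, sd = s), class = "norm_stats")
}

#' Apply (or invert) channel normalization
#'
#' @param trace numeric vector/array of LFP values.
#' @param stats a `norm_stats` from [fit_norm_stats()].
#' @param invert undo the normalization instead.
#' @return normalized (or de-normalized) trace.
#' @export
apply_norm <- function(trace, stats, invert = FALSE) {
  if (invert) trace * stats$sd + stats$mean
  else (trace - stats$mean) / stats$sd
}

#' Normalize every channel of a trial set
#'
#' The statistics are fit on all trials pooled (train and test together),
#' matching the emulated analysis; this mild train/test leakage is
#' intentional and documented. Dead channels raise an error.
#'
#' @param trials a `trial_set`.
#' @return the trial set with normalized LFPs and a `norm_stats` list
#'   attached.
#' @export
normalize_trialset <- function(trials) {
  ns <- lapply(seq_len(dim(trials$lfp)[2]),
               function(ch) fit_norm_stats(trials, ch))
  for (ch in seq_along(ns))
    trials$lfp[, ch, ] <- apply_norm(trials$lfp[, ch, ], ns[[ch]])
  trials$norm_stats <- ns
  trials$normalized <- TRUE
  trials
}

#' Extract one tau-centered epoch from a trial
#'
#' Sample k of the returned vector corresponds to absolute trial time
#' `end_ms + tau - L/2 + (k - 1)` ms: the window rides on the
#' fixation-aligned axis anchored at the trial's saccade end.
#'
#' @param trace the trial's LFP vector for one channel.
#' @param time trial time axis in ms.
#' @param end_ms the trial's saccade end (fixation onset) in trial time.
#' @param window a [window_spec()].
#' @return numeric feature vector of `window$length` samples.
#' @export
extract_epoch <- function(trace, time, end_ms, window) {
  want <- end_ms + window$times
  idx <- match(want, time)
  if (anyNA(idx))
    ps_error(sprintf("window tau=%d extends outside the recorded span",
                     window$tau), "perisacc_epoch_oob")
  trace[idx]
}

#' Build an epoch matrix (trials x features) for one channel and window
#'
#' @param trials a `trial_set` (normalize first with
#'   [normalize_trialset()] for classifier use).
#' @param channel channel index.
#' @param window a [window_spec()].
#' @param events events table giving each trial's `end_ms` (defaults to
#'   the trial set's own events, e.g. ground truth or detected).
#' @param trial_ids trials to include (default all).
#' @return matrix with one row per trial; rownames are trial ids.
#' @export
epoch_matrix <- function(trials, channel, window,
                         events = trials$events,
                         trial_ids = events$trial_id) {
  rows <- lapply(trial_ids, function(k) {
    e <- events[events$trial_id == k, ]
    extract_epoch(trials$lfp[k, channel, ], trials$time, e$end_ms, window)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- trial_ids
  m
}
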