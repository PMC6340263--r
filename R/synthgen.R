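# Synthetic peri-saccadic session generator.
#
# Emulates the outside-in saccade task: 12 saccade directions spaced 30 deg
# around a circle, 7-deg saccades of ~30 ms, multi-channel LFPs sampled at
# 1 kHz with direction-tuned saccade-locked deflections (dip / peak near
# 30-40 ms / second dip near 60-70 ms after fixation onset) embedded in
# 1/f^alpha background noise. snr = 0 produces a pure-noise null session.

ps_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "perisacc_error")))
}

#' Configuration for the synthetic session generator
#'
#' Defaults encode the task geometry and saccade kinematics of the emulated
#' experiment: 12 directions in 30-deg steps, 7-deg outside-in saccades of
#' about 30 ms, LFPs at 1 kHz on a fixation-aligned time axis (t = 0 is
#' saccade end). The raised-cosine speed profile ties amplitude A, duration
#' D and peak speed together (peak = 2A/D); amplitude and duration are the
#' primary parameters, and if `saccade_duration` is `NA` the duration is
#' derived from `peak_speed` instead (D = 2A/peak).
#'
#' @param n_directions number of saccade directions (even spacing).
#' @param trials_per_direction trials per direction.
#' @param n_channels number of LFP channels.
#' @param sample_rate_lfp LFP sampling rate in Hz.
#' @param trial_span integer ms interval (relative to nominal fixation
#'   onset) covered by each trial; must contain the pre-saccadic fixation
#'   window \[-300, -201\] and the post-saccadic window \[200, 299\].
#' @param saccade_amplitude saccade amplitude in deg.
#' @param saccade_duration saccade duration in ms, or `NA` to derive it
#'   from `peak_speed`.
#' @param peak_speed peak eye speed in deg/s (used when duration is `NA`).
#' @param eye_noise_sd fixational position noise SD in deg.
#' @param snr per-channel template RMS over noise RMS; 0 is the null mode
#'   (no saccade-locked signal).
#' @param snr_log_sd SD of per-channel log-normal SNR variation.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param latency_jitter_sd SD (ms) of the trial-to-trial latency jitter of
#'   the true fixation onset, truncated at +/- 10 ms and rounded to 1 ms.
#' @param template_params list controlling the dip/peak/dip template family;
#'   see [gen_template()].
#' @param seed integer seed making the whole session reproducible.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_directions = 12,
                         trials_per_direction = 42,
                         n_channels = 16,
                         sample_rate_lfp = 1000,
                         trial_span = c(-400, 400),
                         saccade_amplitude = 7,
                         saccade_duration = 30,
                         peak_speed = 325,
                         eye_noise_sd = 0.01,
                         snr = 5,
                         snr_log_sd = 0.25,
                         noise_exponent = 1,
                         latency_jitter_sd = 3,
                         template_params = list(),
                         seed = 1L) {
  if (n_directions < 1 || trials_per_direction < 1 || n_channels < 1)
    ps_error("counts must be positive", "perisacc_invalid_config")
  if (sample_rate_lfp <= 0)
    ps_error("sample rate must be positive", "perisacc_invalid_config")
  if (saccade_amplitude <= 0)
    ps_error("saccade amplitude must be positive", "perisacc_invalid_config")
  if (!is.na(saccade_duration) && saccade_duration <= 0)
    ps_error("saccade duration must be positive", "perisacc_invalid_config")
  if (is.na(saccade_duration) && peak_speed <= 0)
    ps_error("peak speed must be positive", "perisacc_invalid_config")
  if (snr < 0)
    ps_error("snr must be >= 0", "perisacc_invalid_config")
  trial_span <- as.integer(round(trial_span))
  if (length(trial_span) != 2 || trial_span[1] >= trial_span[2])
    ps_error("trial_span must be an increasing ms interval",
             "perisacc_invalid_config")
  if (trial_span[1] > -311 || trial_span[2] < 310)
    ps_error(paste("trial_span too short: it must contain the pre-saccadic",
                   "fixation window [-300, -201] and the post-saccadic",
                   "window [200, 299] after up to 10 ms latency jitter"),
             "perisacc_invalid_config")
  if (is.na(saccade_duration))
    saccade_duration <- 2 * saccade_amplitude / peak_speed * 1000
  tp <- utils::modifyList(list(
    lobe_t = c(8, 35, 65),       # ms after fixation onset: dip, peak, dip
    lobe_sd = c(8, 12, 14),      # lobe widths, ms
    lobe_amp = c(-0.6, 1, -0.7), # relative lobe amplitudes
    tuning_kappa = 2,            # von Mises concentration of the tuning
    tuning_floor = 0.35,         # amplitude floor at anti-preferred dirs
    lobe_pref_offset = c(0, 120, 240), # deg between lobe preferred dirs
    latency_mod = 4,             # ms of direction-dependent latency shift
    support = c(-40, 120),       # ms support of the template
    amp_scale = 1,               # overall scale; 0 gives all-zero templates
    zero_mean = FALSE            # force zero-sum templates
  ), template_params)
  structure(list(
    n_directions = as.integer(n_directions),
    trials_per_direction = as.integer(trials_per_direction),
    n_channels = as.integer(n_channels),
    sample_rate_lfp = sample_rate_lfp,
    trial_span = trial_span,
    saccade_amplitude = saccade_amplitude,
    saccade_duration = saccade_duration,
    peak_speed = 2 * saccade_amplitude / (saccade_duration / 1000),
    eye_noise_sd = eye_noise_sd,
    snr = snr,
    snr_log_sd = snr_log_sd,
    noise_exponent = noise_exponent,
    latency_jitter_sd = latency_jitter_sd,
    template_params = tp,
    directions = seq(0, 360 - 360 / n_directions,
                     by = 360 / n_directions),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_directions, " directions x ",
      x$trials_per_direction, " trials x ", x$n_channels, " channels; ",
      "snr ", x$snr, "; span [", x$trial_span[1], ", ", x$trial_span[2],
      "] ms; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Deterministic per-channel tuning parameters
#'
#' Channels get preferred directions spread around the circle with a
#' seed-derived jitter, and log-normal SNR multipliers emulating gain
#' variation across electrodes.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns channel, pref_deg, snr_mult.
#' @export
channel_params <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "channel_params"), {
    n <- cfg$n_channels
    pref <- ((seq_len(n) - 1) * 360 / n +
               stats::runif(n, -180 / n, 180 / n)) %% 360
    mult <- exp(stats::rnorm(n, 0, cfg$snr_log_sd))
    data.frame(channel = seq_len(n), pref_deg = pref, snr_mult = mult)
  })
}

#' Generate an eye-position and eye-speed trace for one trial
#'
#' Outside-in geometry: the eye starts on a circle of radius
#' `saccade_amplitude` at angle `direction + 180` and lands at the display
#' center, so the displacement vector points along `direction` (component 1
#' is horizontal, component 2 vertical, angles counter-clockwise from the
#' positive horizontal axis). The speed pulse is a raised cosine whose
#' support is the saccade duration and whose integral is the amplitude;
#' position is integrated in closed form so the displacement is exact.
#'
#' @param direction saccade direction in deg (one of `cfg$directions`).
#' @param cfg a [synth_config()].
#' @param end_ms true saccade end (fixation onset) time on the trial axis.
#' @param seed optional seed for the fixational position noise; `NULL`
#'   draws from the current RNG stream.
#' @return list with `time` (ms), `pos` (2 x T deg), `speed` (deg/s,
#'   noise-free analytic profile), `onset_ms`, `end_ms`.
#' @export
gen_eye_trace <- function(direction, cfg, end_ms = 0, seed = NULL) {
  if (!any(abs(wrap_angle(direction - cfg$directions)) < 1e-9))
    ps_error("direction not in configured set", "perisacc_invalid_config")
  tm <- seq(cfg$trial_span[1], cfg$trial_span[2])
  dur <- cfg$saccade_duration
  onset <- end_ms - dur
  a <- cfg$saccade_amplitude
  th <- direction * pi / 180
  u <- pmin(pmax((tm - onset) / dur, 0), 1)
  frac <- u - sin(2 * pi * u) / (2 * pi)       # position fraction in [0,1]
  speed <- a / (dur / 1000) * (1 - cos(2 * pi * u))  # deg/s, peak 2A/D
  start <- -a * c(cos(th), sin(th))
  pos <- rbind(start[1] + a * cos(th) * frac,
               start[2] + a * sin(th) * frac)
  noise <- with_seed(seed,
    matrix(stats::rnorm(2 * length(tm), 0, cfg$eye_noise_sd), nrow = 2))
  list(time = tm, pos = pos + noise, speed = speed,
       onset_ms = onset, end_ms = end_ms)
}

#' Direction-tuned saccade-locked LFP template
#'
#' A sum of three Gaussian lobes (dip, peak, second dip) on the
#' fixation-aligned axis, amplitude-modulated by a von Mises function of
#' the angle between the saccade direction and a lobe-specific preferred
#' direction, with a small direction-dependent latency shift. Neighboring
#' directions therefore produce correlated waveforms while distant
#' directions decorrelate, and the template is smoothly tapered to zero
#' outside its support. Deterministic given (direction, channel, cfg).
#' Waveforms are normalized so the direction-averaged RMS over the support
#' is 1 for every channel; the per-channel SNR scaling happens in
#' [gen_trialset()].
#'
#' @param direction saccade direction in deg.
#' @param channel channel index.
#' @param cfg a [synth_config()].
#' @return numeric vector over the trial time axis (t = 0 at fixation
#'   onset), zero outside the template support.
#' @export
gen_template <- function(direction, channel, cfg) {
  tm <- seq(cfg$trial_span[1], cfg$trial_span[2])
  chp <- channel_params(cfg)
  pref <- chp$pref_deg[channel]
  raw <- template_raw(direction, pref, tm, cfg$template_params)
  # direction-averaged RMS over the support, for SNR-neutral tuning
  sup <- cfg$template_params$support
  insup <- tm >= sup[1] & tm <= sup[2]
  ms <- mean(vapply(cfg$directions, function(d) {
    w <- template_raw(d, pref, tm, cfg$template_params)
    mean(w[insup]^2)
  }, numeric(1)))
  if (ms <= 0) return(raw) # amp_scale 0: all-zero template
  raw / sqrt(ms)
}

# unscaled template family (internal)
template_raw <- function(direction, pref_deg, tm, tp) {
  rel <- (direction - pref_deg) * pi / 180
  shift <- tp$latency_mod * sin(rel)
  k <- tp$tuning_kappa
  w <- numeric(length(tm))
  for (i in seq_along(tp$lobe_t)) {
    tune <- tp$tuning_floor + (1 - tp$tuning_floor) *
      exp(k * (cos(rel - tp$lobe_pref_offset[i] * pi / 180) - 1))
    w <- w + tp$lobe_amp[i] * tune *
      exp(-(tm - tp$lobe_t[i] - shift)^2 / (2 * tp$lobe_sd[i]^2))
  }
  # raised-cosine taper to zero outside the support
  sup <- tp$support
  taper <- rep(0, length(tm))
  inside <- tm >= sup[1] & tm <= sup[2]
  x <- (tm[inside] - sup[1]) / (sup[2] - sup[1])
  taper[inside] <- 0.5 * (1 - cos(2 * pi * pmin(x, 1 - x) / 0.2))
  taper[inside][x >= 0.1 & x <= 0.9] <- 1
  w <- w * taper * tp$amp_scale
  if (isTRUE(tp$zero_mean) && any(taper > 0) && tp$amp_scale != 0)
    w <- w - sum(w) / sum(taper) * taper
  w
}

#' Spectrally shaped 1/f^alpha Gaussian noise
#'
#' @param n number of samples.
#' @param alpha spectral exponent (power ~ 1/f^alpha); 0 gives white noise.
#' @return numeric vector with (population) SD 1 and mean 0.
#' @export
gen_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  ctr <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  if (alpha == 0) return(ctr(w))
  freq <- pmin(seq_len(n - 1), n - seq_len(n - 1)) # symmetric bin index
  scale <- c(0, freq^(-alpha / 2))                 # DC removed
  v <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  ctr(v)
}

#' Generate a full synthetic trial set with ground truth
#'
#' Each trial is 1/f^alpha background noise (unit RMS per channel) plus the
#' direction- and channel-specific template inserted at the true fixation
#' onset, which is jittered around the nominal t = 0 by a truncated
#' Gaussian (rounded to the 1 ms grid). The template is scaled by the
#' per-channel SNR. With `snr = 0` no signal is inserted (null mode).
#'
#' @param cfg a [synth_config()].
#' @return list with elements `trials` (a `trial_set`: `lfp`
#'   trials x channels x time, `eye` trials x 2 x time, `time`, `events`
#'   data.frame, `sample_rate`, `cfg`) and `truth` (`events` plus the
#'   per-channel, per-direction template matrix used).
#' @export
gen_trialset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  tm <- seq(cfg$trial_span[1], cfg$trial_span[2])
  nt <- cfg$n_directions * cfg$trials_per_direction
  nc <- cfg$n_channels
  chp <- channel_params(cfg)
  dirs <- rep(cfg$directions, each = cfg$trials_per_direction)

  templates <- array(0, dim = c(nc, cfg$n_directions, length(tm)),
                     dimnames = list(NULL, paste0("d", cfg$directions), NULL))
  for (ch in seq_len(nc))
    for (di in seq_along(cfg$directions))
      templates[ch, di, ] <- gen_template(cfg$directions[di], ch, cfg)

  with_seed(derive_seed(cfg$seed, "gen_trialset"), {
    jit <- round(pmin(pmax(
      stats::rnorm(nt, 0, cfg$latency_jitter_sd), -10), 10))
    lfp <- array(0, dim = c(nt, nc, length(tm)))
    eye <- array(0, dim = c(nt, 2, length(tm)))
    for (k in seq_len(nt)) {
      di <- match(dirs[k], cfg$directions)
      et <- gen_eye_trace(dirs[k], cfg, end_ms = jit[k])
      eye[k, , ] <- et$pos
      for (ch in seq_len(nc)) {
        sig <- 0
        if (cfg$snr > 0) {
          tmpl <- templates[ch, di, ]
          sig <- cfg$snr * chp$snr_mult[ch] * shift_trace(tmpl, jit[k])
        }
        lfp[k, ch, ] <- gen_noise(length(tm), cfg$noise_exponent) + sig
      }
    }
    events <- data.frame(
      trial_id = seq_len(nt),
      onset_ms = jit - cfg$saccade_duration,
      end_ms = jit,
      direction_deg = dirs
    )
    trials <- structure(list(
      lfp = lfp, eye = eye, time = tm, events = events,
      sample_rate = cfg$sample_rate_lfp, sample_rate_eye = 1000,
      normalized = FALSE, cfg = cfg
    ), class = "trial_set")
    list(trials = trials,
         truth = list(events = events, templates = templates,
                      channel_params = chp))
  })
}

# integer-ms shift of a trace, zero-padded (internal)
shift_trace <- function(x, by) {
  by <- as.integer(round(by))
  n <- length(x)
  out <- numeric(n)
  if (by >= 0) out[(1 + by):n] <- x[1:(n - by)]
  else out[1:(n + by)] <- x[(1 - by):n]
  out
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set> ", dim(x$lfp)[1], " trials x ", dim(x$lfp)[2],
      " channels x ", dim(x$lfp)[3], " samples at ", x$sample_rate,
      " Hz; t in [", x$time[1], ", ", x$time[length(x$time)], "] ms\n",
      sep = "")
  invisible(x)
}
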