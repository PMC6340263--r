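# Fixation-onset timing analysis: families of classifiers across
# tau_train, bias-corrected tau_test sweeps, per-trial best-window votes,
# and RMS error curves.

#' Training-window grid for a given window length
#'
#' All centers whose windows lie within the analyzed span -100..+99 ms:
#' `seq(-100 + L/2, 99 - L/2)`. For 100 ms windows this is -50..49; for
#' 10 ms windows the leftmost center is -95 (window starting at -100).
#'
#' @param length window length in ms (even).
#' @return integer vector of training-window centers.
#' @export
tau_train_grid <- function(length = 100) {
  window_spec(0, length) # validates length
  seq(-100 + length / 2, 99 - length / 2)
}

#' Bias-corrected test-window centers for a training center
#'
#' The test range follows two rules: it is symmetric about `tau_train`,
#' and for every training center it spans the whole training grid -- so a
#' trained pattern can be found equally far on either side and edge
#' effects cannot bias the votes. For 100 ms windows the range is
#' `tau_train - 100 .. tau_train + 99` (200 centers).
#'
#' @param tau_train training-window center (must lie on [tau_train_grid()]).
#' @param length window length in ms.
#' @return integer vector of test centers.
#' @export
tau_test_range <- function(tau_train, length = 100) {
  grid <- tau_train_grid(length)
  if (!tau_train %in% grid)
    ps_error(sprintf("tau_train %s is off the training grid %d..%d",
                     tau_train, grid[1], grid[length(grid)]),
             "perisacc_invalid_config")
  h <- length / 2
  seq(tau_train - 2 * h, tau_train + 2 * h - 1)
}

#' Slide a trained classifier across test windows of one trial
#'
#' Extracts the epoch at every test center and scores it by its signed
#' distance to the hyperplane, yielding the s-curve s(tau_test).
#'
#' @param clf a `linear_classifier` trained at some tau_train.
#' @param trace the trial's (normalized) LFP vector for the classifier's
#'   channel.
#' @param time trial time axis in ms.
#' @param end_ms the trial's fixation onset in trial time.
#' @param taus test centers (default [tau_test_range()] of
#'   `clf$meta$tau_train`).
#' @param length window length in ms.
#' @return named numeric vector s(tau_test).
#' @export
slide_classify <- function(clf, trace, time, end_ms,
                           taus = tau_test_range(clf$meta$tau_train, length),
                           length = 100) {
  h <- length / 2
  idx0 <- match(end_ms + taus[1] - h, time)
  last <- match(end_ms + taus[base::length(taus)] + h - 1, time)
  if (is.na(idx0) || is.na(last))
    ps_error("test windows extend outside the recorded span",
             "perisacc_epoch_oob")
  # all epochs share samples; build the epoch matrix by offset indexing
  ep <- vapply(seq_along(taus), function(i)
    trace[(idx0 + i - 1):(idx0 + i - 2 + length)], numeric(length))
  s <- s_value(clf, t(ep))
  names(s) <- taus
  s
}

#' Best test-window vote from an s-curve
#'
#' The vote is the tau_test with the largest s-value; ties are broken
#' toward the center nearest `tau_train`, then toward the earlier center.
#'
#' @param s_curve named s-curve from [slide_classify()].
#' @param tau_train the training center.
#' @return the winning tau_test (ms).
#' @export
vote <- function(s_curve, tau_train) {
  taus <- as.numeric(names(s_curve))
  best <- which(s_curve == max(s_curve))
  if (length(best) > 1) {
    d <- abs(taus[best] - tau_train)
    best <- best[d == min(d)]
    best <- best[which.min(taus[best])]
  }
  taus[best]
}

#' RMS error of votes around the training center
#'
#' @param votes vector of per-trial votes (ms).
#' @param tau_train training center (ms).
#' @return sqrt(mean((vote - tau_train)^2)).
#' @export
rms_error <- function(votes, tau_train) {
  sqrt(mean((votes - tau_train)^2))
}

#' RMS of votes drawn uniformly from the test range (analytic null)
#'
#' Under pure noise the vote is uniform over the symmetric test range, so
#' the expected squared error is the mean square of the offsets
#' `-2h .. 2h-1`; this is the reference value timing performance is
#' compared against.
#'
#' @param length window length in ms.
#' @return RMS (ms) of the uniform-vote null.
#' @export
uniform_vote_rms <- function(length = 100) {
  h <- length / 2
  off <- seq(-2 * h, 2 * h - 1)
  sqrt(mean(off^2))
}

#' Temporal train/test sweep for one channel and direction
#'
#' For each training center, an SVM separates the tau_train epochs of the
#' selected (positive-class) trials from the fixation epochs at `neg_tau`;
#' under leave-one-out, each held-out trial's LFP is slid across the
#' bias-corrected test range and votes for the tau_test with the largest
#' s-value. Reports per-trial votes, the mean vote, and the RMS error per
#' training center.
#'
#' @param trials a normalized `trial_set`.
#' @param channel channel index.
#' @param direction saccade direction (deg) of the positive-class trials,
#'   or `NULL` for all directions.
#' @param tau_train training centers (default the full grid).
#' @param length window length in ms.
#' @param neg_tau center of the fixation (negative-class) window.
#' @param cost soft-margin cost.
#' @param events events table (default the trial set's own).
#' @return data.frame of class `sweep_result` with one row per
#'   (tau_train, trial): columns tau_train, trial_id, vote; plus
#'   attribute `summary` (tau_train, mean_vote, rms).
#' @export
tau_sweep <- function(trials, channel, direction = NULL,
                      tau_train = tau_train_grid(length), length = 100,
                      neg_tau = 250, cost = 1, events = trials$events) {
  ids <- events$trial_id
  if (!is.null(direction))
    ids <- ids[events$direction_deg == direction]
  if (length(ids) < 2)
    ps_error("need >= 2 positive-class trials", "perisacc_insufficient_class")
  negw <- window_spec(neg_tau, length)
  neg <- epoch_matrix(trials, channel, negw, events, ids)
  tm <- trials$time
  rows <- list()
  for (tt in tau_train) {
    posw <- window_spec(tt, length)
    pos <- epoch_matrix(trials, channel, posw, events, ids)
    taus <- tau_test_range(tt, length)
    votes <- vapply(seq_along(ids), function(i) {
      clf <- train_linear_svm(pos[-i, , drop = FALSE],
                              neg[-i, , drop = FALSE], cost = cost,
                              meta = list(tau_train = tt, channel = channel))
      e <- events[events$trial_id == ids[i], ]
      sc <- slide_classify(clf, trials$lfp[ids[i], channel, ], tm,
                           e$end_ms, taus, length)
      vote(sc, tt)
    }, numeric(1))
    rows[[as.character(tt)]] <- data.frame(
      tau_train = tt, trial_id = ids, vote = votes)
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$tau_train), function(d)
    data.frame(tau_train = d$tau_train[1], mean_vote = mean(d$vote),
               sd_vote = stats::sd(d$vote),
               rms = rms_error(d$vote, d$tau_train[1]))))
  attr(out, "summary") <- summ[order(summ$tau_train), ]
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Multi-channel temporal sweep summary
#'
#' Runs [tau_sweep()] on each channel and returns per-channel mean votes
#' and RMS errors plus the channel-averaged RMS curve.
#'
#' @inheritParams tau_sweep
#' @param channels channel indices.
#' @return list with `per_channel` (channel, tau_train, mean_vote, rms),
#'   `rms_curve` (tau_train, mean_rms averaged over channels), and
#'   `votes` (all per-trial votes).
#' @export
sweep_channels <- function(trials, channels, direction = NULL,
                           tau_train = tau_train_grid(length),
                           length = 100, neg_tau = 250, cost = 1,
                           events = trials$events) {
  res <- lapply(channels, function(ch) {
    sw <- tau_sweep(trials, ch, direction, tau_train, length,
                    neg_tau, cost, events)
    cbind(channel = ch, as.data.frame(sw))
  })
  votes <- do.call(rbind, res)
  per_channel <- do.call(rbind, lapply(
    split(votes, list(votes$channel, votes$tau_train)), function(d)
      data.frame(channel = d$channel[1], tau_train = d$tau_train[1],
                 mean_vote = mean(d$vote),
                 rms = rms_error(d$vote, d$tau_train[1]))))
  rms_curve <- do.call(rbind, lapply(
    split(per_channel, per_channel$tau_train), function(d)
      data.frame(tau_train = d$tau_train[1], mean_rms = mean(d$rms))))
  list(per_channel = per_channel[order(per_channel$channel,
                                       per_channel$tau_train), ],
       rms_curve = rms_curve[order(rms_curve$tau_train), ],
       votes = votes)
}
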