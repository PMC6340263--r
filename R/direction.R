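# Direction-resolved analyses: per-direction saccade/fixation AUCs,
# one-vs-rest and 12-way direction classification with circular direction
# estimates and angular-error summaries, the LFP-shape permutation test,
# and bootstrap confidence bands for mean LFPs.

#' Saccade-vs-fixation AUC restricted to one saccade direction
#'
#' Leave-one-out s-values computed on the trials of a single direction
#' (positive class: peri-saccadic window; negative class: fixation window
#' at `neg_tau`), then ROC/AUC.
#'
#' @param trials a normalized `trial_set`.
#' @param channel channel index.
#' @param direction saccade direction in deg.
#' @param window positive-class [window_spec()] (default tau = 25).
#' @param neg_tau fixation window center.
#' @param cost soft-margin cost.
#' @param events events table.
#' @return a `roc_curve`.
#' @export
per_direction_auc <- function(trials, channel, direction,
                              window = window_spec(25), neg_tau = 250,
                              cost = 1, events = trials$events) {
  ids <- events$trial_id[events$direction_deg == direction]
  pos <- epoch_matrix(trials, channel, window, events, ids)
  neg <- epoch_matrix(trials, channel, window_spec(neg_tau, window$length),
                      events, ids)
  tab <- loo_svalues(pos, neg, cost = cost)
  roc_auc(tab$s[tab$true_class == "pos"], tab$s[tab$true_class == "neg"])
}

#' One-direction-vs-all-other-directions s-values and AUC
#'
#' The positive class is the tau = 25 epochs of one direction's trials;
#' the negative class the same window from all other directions.
#' Leave-one-out s-values, then AUC: the probability that a saccade in the
#' target direction outscores one in any other direction.
#'
#' @inheritParams per_direction_auc
#' @return list with `auc`, `roc`, and the s-value `table`.
#' @export
one_vs_rest_auc <- function(trials, channel, direction,
                            window = window_spec(25), cost = 1,
                            events = trials$events) {
  pid <- events$trial_id[events$direction_deg == direction]
  nid <- events$trial_id[events$direction_deg != direction]
  if (length(pid) < 2 || length(nid) < 2)
    ps_error("need >= 2 trials inside and outside the target direction",
             "perisacc_insufficient_class")
  pos <- epoch_matrix(trials, channel, window, events, pid)
  neg <- epoch_matrix(trials, channel, window, events, nid)
  tab <- loo_svalues(pos, neg, cost = cost)
  roc <- roc_auc(tab$s[tab$true_class == "pos"],
                 tab$s[tab$true_class == "neg"])
  list(auc = roc$auc, roc = roc, table = tab)
}

#' Multiclass saccade-direction decoding by pairwise voting
#'
#' Builds all pairwise direction classifiers (66 for 12 directions) on
#' each training fold of a stratified k-fold split and predicts each
#' held-out trial's direction as the one winning the most pairwise
#' contests; ties are broken by the larger sum of winning-margin s-values.
#'
#' @param trials a normalized `trial_set`.
#' @param channel channel index.
#' @param window [window_spec()] for the decoding epoch (default tau = 25).
#' @param k_folds number of cross-validation folds (default 30).
#' @param cost soft-margin cost.
#' @param seed seed for the stratified fold assignment.
#' @param events events table.
#' @return data.frame (trial_id, true_deg, predicted_deg).
#' @export
multiway_classify <- function(trials, channel, window = window_spec(25),
                              k_folds = 30, cost = 1, seed = 1,
                              events = trials$events) {
  dirs <- sort(unique(events$direction_deg))
  ids <- events$trial_id
  ep <- epoch_matrix(trials, channel, window, events, ids)
  y <- events$direction_deg[match(ids, events$trial_id)]
  fold <- with_seed(seed, {
    f <- integer(length(ids))
    for (d in dirs) {
      i <- which(y == d)
      f[i] <- sample(rep_len(seq_len(k_folds), length(i)))
    }
    f
  })
  for (k in seq_len(k_folds))
    if (!all(dirs %in% y[fold != k]))
      ps_error("a training fold lacks some direction; reduce k_folds",
               "perisacc_stratification")
  pred <- numeric(length(ids))
  pairs <- utils::combn(seq_along(dirs), 2)
  for (k in seq_len(k_folds)) {
    test <- which(fold == k)
    if (length(test) == 0) next
    wins <- matrix(0, length(test), length(dirs))
    margin <- matrix(0, length(test), length(dirs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      tri <- which(fold != k & y == dirs[i])
      trj <- which(fold != k & y == dirs[j])
      clf <- train_linear_svm(ep[tri, , drop = FALSE],
                              ep[trj, , drop = FALSE], cost = cost)
      s <- s_value(clf, ep[test, , drop = FALSE])
      wi <- s > 0
      wins[wi, i] <- wins[wi, i] + 1
      wins[!wi, j] <- wins[!wi, j] + 1
      margin[wi, i] <- margin[wi, i] + s[wi]
      margin[!wi, j] <- margin[!wi, j] - s[!wi]
    }
    pred[test] <- vapply(seq_along(test), function(t) {
      best <- which(wins[t, ] == max(wins[t, ]))
      if (length(best) > 1) best <- best[which.max(margin[t, best])]
      dirs[best]
    }, numeric(1))
  }
  data.frame(trial_id = ids, true_deg = y, predicted_deg = pred)
}

#' Circular mean of angles in degrees
#'
#' @param angles numeric vector of angles (deg).
#' @return mean direction in \[0, 360).
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0)
    ps_error("empty angle set", "perisacc_insufficient_data")
  th <- angles * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12)
    ps_error("zero resultant: circular mean undefined",
             "perisacc_undefined_mean")
  ang <- (atan2(s, c) * 180 / pi) %% 360
  if (ang > 360 - 1e-9) 0 else ang
}

#' Angular-error summary of per-direction estimates
#'
#' Errors are wrapped differences estimate - truth in (-180, 180\];
#' the summary reports the mean, RMS, SD, min and max of the absolute
#' errors across directions.
#'
#' @param estimates estimated direction (deg) per direction.
#' @param truths true directions (deg).
#' @return data.frame row: avg_error, rms_error, sd_error, min_error,
#'   max_error (deg).
#' @export
direction_error_stats <- function(estimates, truths) {
  err <- abs(wrap_angle(estimates - truths))
  data.frame(avg_error = mean(err),
             rms_error = sqrt(mean(err^2)),
             sd_error = stats::sd(err),
             min_error = min(err),
             max_error = max(err))
}

#' Mean pairwise Pearson correlation of epochs within a direction
#'
#' @param epochs epoch matrix (>= 2 rows; no zero-variance row).
#' @return mean Pearson r over all unordered trial pairs.
#' @export
within_direction_corr <- function(epochs) {
  epochs <- rbind(epochs)
  if (nrow(epochs) < 2)
    ps_error("need >= 2 epochs", "perisacc_insufficient_data")
  if (any(apply(epochs, 1, stats::sd) == 0))
    ps_error("zero-variance epoch", "perisacc_degenerate_epoch")
  cm <- stats::cor(t(epochs))
  mean(cm[upper.tri(cm)])
}

#' Permutation test for a difference in LFP shape between two directions
#'
#' The observed statistic is the average of the two within-direction mean
#' pairwise correlations. Under the null the trials are exchangeable: the
#' pooled trials are randomly reassigned to two groups of the original
#' sizes, and each reassignment contributes the average of the two group
#' statistics. The upper-tail p-value (within-direction coherence higher
#' than shuffled coherence) uses add-one smoothing:
#' p = (1 + #\{null >= observed\}) / (n_perm + 1). Because pairwise
#' correlations of fixed trials do not change under reassignment, the
#' pooled correlation matrix is computed once and permutations only
#' re-average its entries.
#'
#' @param epochs_a,epochs_b epoch matrices for the two directions.
#' @param n_perm number of random reassignments.
#' @param seed RNG seed.
#' @param exact if `TRUE`, enumerate all balanced reassignments instead of
#'   sampling (feasible for small groups); p is then the exact fraction
#'   of reassignments with statistic >= observed.
#' @return list: observed, null (vector), p, n_perm.
#' @export
shape_permutation_test <- function(epochs_a, epochs_b, n_perm = 10000,
                                   seed = 1, exact = FALSE) {
  epochs_a <- rbind(epochs_a); epochs_b <- rbind(epochs_b)
  na <- nrow(epochs_a); nb <- nrow(epochs_b)
  if (na < 2 || nb < 2)
    ps_error("need >= 2 trials per direction", "perisacc_insufficient_data")
  cm <- stats::cor(t(rbind(epochs_a, epochs_b)))
  grp_mean <- function(idx) {
    sub <- cm[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  n <- na + nb
  stat <- function(ia) (grp_mean(ia) + grp_mean(setdiff(seq_len(n), ia))) / 2
  observed <- stat(seq_len(na))
  if (exact) {
    combs <- utils::combn(n, na)
    null <- apply(combs, 2, stat)
    p <- mean(null >= observed)
    return(list(observed = observed, null = null, p = p,
                n_perm = ncol(combs)))
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(sample(n, na)), numeric(1)))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  list(observed = observed, null = null, p = p, n_perm = n_perm)
}

#' Shape permutation tests for all direction pairs with Bonferroni control
#'
#' Runs [shape_permutation_test()] on every unordered pair of directions
#' for one channel, flagging significance at `alpha` after Bonferroni
#' correction over the pairs (66 for 12 directions).
#'
#' @param trials a normalized `trial_set`.
#' @param channel channel index.
#' @param window epoch window (default tau = 25).
#' @param n_perm permutations per pair.
#' @param alpha family-wise significance level.
#' @param seed RNG seed.
#' @param events events table.
#' @return data.frame (dir_a, dir_b, observed, p, significant_bonferroni).
#' @export
shape_permutation_all <- function(trials, channel,
                                  window = window_spec(25),
                                  n_perm = 10000, alpha = 0.05, seed = 1,
                                  events = trials$events) {
  dirs <- sort(unique(events$direction_deg))
  pairs <- utils::combn(dirs, 2)
  eps <- lapply(dirs, function(d)
    epoch_matrix(trials, channel, window, events,
                 events$trial_id[events$direction_deg == d]))
  names(eps) <- dirs
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- as.character(pairs[1, p]); b <- as.character(pairs[2, p])
    r <- shape_permutation_test(eps[[a]], eps[[b]], n_perm,
                                seed = derive_seed(seed, paste(a, b)))
    data.frame(dir_a = pairs[1, p], dir_b = pairs[2, p],
               observed = r$observed, p = r$p)
  })
  res <- do.call(rbind, out)
  res$significant_bonferroni <- res$p < alpha / nrow(res)
  res
}

#' Percentile bootstrap confidence band for the mean epoch waveform
#'
#' Resamples trials with replacement and reports per-sample percentile
#' intervals for the mean LFP, plus the per-sample SD band.
#'
#' @param epochs epoch matrix (>= 2 rows).
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return data.frame (sample, mean, lower, upper, sd).
#' @export
bootstrap_mean_ci <- function(epochs, n_boot = 2000, level = 0.95,
                              seed = 1) {
  epochs <- rbind(epochs)
  n <- nrow(epochs)
  if (n < 2)
    ps_error("need >= 2 trials", "perisacc_insufficient_data")
  mu <- colMeans(epochs)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    colMeans(epochs[sample(n, n, replace = TRUE), , drop = FALSE]),
    numeric(ncol(epochs))))
  a <- (1 - level) / 2
  qs <- apply(boots, 1, stats::quantile, probs = c(a, 1 - a))
  data.frame(sample = seq_len(ncol(epochs)), mean = mu,
             lower = qs[1, ], upper = qs[2, ],
             sd = apply(epochs, 2, stats::sd))
}
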