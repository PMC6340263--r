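test_that("circular mean matches the vector-sum oracle and wraps", {
  expect_equal(circular_mean(c(90, 90)), 90)
  expect_equal(circular_mean(c(350, 10)), 0)
  expect_equal(circular_mean(c(0, 90)), 45)
  expect_error(circular_mean(c(0, 180)), class = "perisacc_undefined_mean")
  expect_error(circular_mean(numeric(0)),
               class = "perisacc_insufficient_data")
})

test_that("angular error statistics wrap across 0/360", {
  st <- direction_error_stats(c(0, 90), c(0, 90))
  expect_equal(unlist(st), c(avg_error = 0, rms_error = 0, sd_error = 0,
                             min_error = 0, max_error = 0))
  st2 <- direction_error_stats(c(10, 350), c(0, 0))
  expect_equal(st2$avg_error, 10)
  expect_equal(st2$rms_error, 10)
  expect_equal(direction_error_stats(355, 5)$avg_error, 10) # wrap, not 350
})

test_that("within-direction correlation averages all trial pairs", {
  a <- rbind(c(0, 1, 2), c(0, 2, 4))
  expect_equal(within_direction_corr(a), 1)
  expect_equal(within_direction_corr(rbind(c(0, 1, 2), c(2, 1, 0))), -1)
  three <- rbind(c(0, 1, 2), c(0, 2, 4), c(2, 1, 0))
  expect_equal(within_direction_corr(three), (1 - 1 - 1) / 3)
  expect_error(within_direction_corr(rbind(c(1, 1, 1), c(0, 1, 2))),
               class = "perisacc_degenerate_epoch")
  expect_error(within_direction_corr(rbind(c(0, 1, 2))),
               class = "perisacc_insufficient_data")
})

test_that("permutation p-values agree with exhaustive enumeration and use
           add-one smoothing", {
  set.seed(4)
  a <- rbind(c(1, 2, 3, 1), c(1, 2, 4, 1)) + matrix(rnorm(8, 0, 0.05), 2)
  b <- rbind(c(3, 1, 0, 2), c(3, 1, 1, 2)) + matrix(rnorm(8, 0, 0.05), 2)
  ex <- shape_permutation_test(a, b, exact = TRUE)
  expect_equal(ex$n_perm, choose(4, 2))
  mc <- shape_permutation_test(a, b, n_perm = 4000, seed = 9)
  expect_lt(abs(mc$p - ex$p), 0.05)
  # observed above every null draw -> smallest attainable p
  if (all(mc$null < mc$observed))
    expect_equal(mc$p, 1 / (mc$n_perm + 1))
  expect_error(shape_permutation_test(a[1, , drop = FALSE], b),
               class = "perisacc_insufficient_data")
})

test_that("permutation test holds its size under the null", {
  n_rep <- 120
  ps <- vapply(seq_len(n_rep), function(r) {
    set.seed(3000 + r)
    tmpl <- sin(seq(0, 3 * pi, length.out = 40))
    mk <- function(n) t(replicate(n, tmpl + rnorm(40, 0, 1)))
    shape_permutation_test(mk(6), mk(6), n_perm = 199,
                           seed = 7000 + r)$p
  }, numeric(1))
  rej <- mean(ps <= 0.05)
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
  # super-uniformity: P(p <= a) <= a + MC slack on a grid
  for (a in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / n_rep))
})

test_that("Bonferroni correction controls family-wise error in null
           simulations", {
  n_rep <- 25
  fw <- vapply(seq_len(n_rep), function(r) {
    cfg <- synth_config(n_directions = 6, trials_per_direction = 4,
                        n_channels = 1, snr = 0, seed = 500 + r,
                        trial_span = c(-320, 320))
    g <- gen_trialset(cfg)
    tr <- normalize_trialset(g$trials)
    res <- shape_permutation_all(tr, 1, n_perm = 499, seed = 600 + r,
                                 events = g$truth$events)
    any(res$significant_bonferroni)
  }, logical(1))
  expect_lte(mean(fw), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("strongly different LFP shapes are detected as significant", {
  ss <- small_session()
  res <- shape_permutation_test(
    epoch_matrix(ss$trials, 1, window_spec(25),
                 trial_ids = which(ss$truth$events$direction_deg == 0)),
    epoch_matrix(ss$trials, 1, window_spec(25),
                 trial_ids = which(ss$truth$events$direction_deg == 180)),
    n_perm = 999, seed = 5)
  expect_lte(res$p, 0.01)
})

test_that("one-vs-rest direction classifiers behave at the information
           extremes", {
  # untuned templates: no direction information, AUC near chance
  cfg <- synth_config(n_directions = 4, trials_per_direction = 8,
                      n_channels = 1, seed = 31,
                      template_params = list(tuning_kappa = 0,
                                             tuning_floor = 1,
                                             latency_mod = 0))
  g <- gen_trialset(cfg)
  tr <- normalize_trialset(g$trials)
  aucs <- vapply(cfg$directions, function(d)
    one_vs_rest_auc(tr, 1, d, events = g$truth$events)$auc, numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.2))
  # strongly tuned high-SNR templates: high AUC for every direction
  cfg2 <- synth_config(trials_per_direction = 10, n_channels = 1,
                       seed = 7, snr = 8,
                       template_params = list(tuning_kappa = 1.5,
                                              tuning_floor = 0,
                                              latency_mod = 8))
  g2 <- gen_trialset(cfg2)
  tr2 <- normalize_trialset(g2$trials)
  aucs2 <- vapply(cfg2$directions, function(d)
    one_vs_rest_auc(tr2, 1, d, events = g2$truth$events)$auc, numeric(1))
  expect_true(all(aucs2 >= 0.9))
})

test_that("pairwise-vote multiclass decoding separates distinct templates
           and confuses identical ones", {
  ss <- small_session()
  mw <- multiway_classify(ss$trials, 1, k_folds = 8, seed = 11,
                          events = ss$truth$events)
  expect_gte(mean(mw$predicted_deg == mw$true_deg), 0.7)
  est <- vapply(split(mw, mw$true_deg),
                function(d) circular_mean(d$predicted_deg), numeric(1))
  errs <- abs(wrap_angle(as.numeric(names(est)) - est))
  expect_true(all(errs <= 15))
  # a direction with a single trial cannot appear in every training fold
  ev1 <- ss$truth$events
  ev1 <- ev1[ev1$direction_deg != 0 | ev1$trial_id == ev1$trial_id[1], ]
  expect_error(multiway_classify(ss$trials, 1, k_folds = 4, events = ev1),
               class = "perisacc_stratification")

  # two directions with identical templates split their trials between the
  # two labels while distinct directions stay accurate
  time <- -350:350
  n_per <- 6; dirs <- c(0, 90, 180, 270)
  tpl <- list(`0` = sin(2 * pi * (time + 25) / 60) * exp(-(time - 25)^2 / 800),
              `90` = cos(2 * pi * (time - 10) / 45) * exp(-(time - 30)^2 / 900))
  tpl$`180` <- rev(tpl$`0`) ; tpl$`270` <- tpl$`180`   # identical pair
  set.seed(12)
  lfp <- array(0, dim = c(length(dirs) * n_per, 1, length(time)))
  y <- rep(dirs, each = n_per)
  for (k in seq_along(y))
    lfp[k, 1, ] <- 4 * tpl[[as.character(y[k])]] + rnorm(length(time))
  ev <- data.frame(trial_id = seq_along(y), onset_ms = -30, end_ms = 0,
                   direction_deg = y)
  toy <- structure(list(lfp = lfp, time = time, events = ev,
                        sample_rate = 1000), class = "trial_set")
  mwt <- multiway_classify(toy, 1, k_folds = 3, seed = 2, events = ev)
  distinct <- mwt$true_deg %in% c(0, 90)
  expect_gte(mean(mwt$predicted_deg[distinct] == mwt$true_deg[distinct]),
             0.9)
  twin <- mwt$true_deg %in% c(180, 270)
  expect_true(all(mwt$predicted_deg[twin] %in% c(180, 270)))
  expect_gt(sum(mwt$predicted_deg[twin] == 180), 0)
  expect_gt(sum(mwt$predicted_deg[twin] == 270), 0)
})

test_that("bootstrap bands bracket the mean and shrink with n", {
  same <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  ci <- bootstrap_mean_ci(same, n_boot = 100, seed = 1)
  expect_equal(ci$lower, ci$mean)
  expect_equal(ci$upper, ci$mean)
  set.seed(8)
  big <- matrix(rnorm(64 * 10), 64)
  ci16 <- bootstrap_mean_ci(big[1:16, ], n_boot = 500, seed = 2)
  ci64 <- bootstrap_mean_ci(big, n_boot = 500, seed = 2)
  expect_true(all(ci64$lower <= ci64$mean & ci64$mean <= ci64$upper))
  expect_lt(mean(ci64$upper - ci64$lower),
            mean(ci16$upper - ci16$lower))
})
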