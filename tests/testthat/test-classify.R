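test_that("the margin QP recovers hand-solved hyperplanes", {
  # 1-D symmetric: boundary at 0, unit weight
  clf <- train_linear_svm(matrix(1), matrix(-1), cost = 1e6)
  expect_equal(clf$weights, 1, tolerance = 1e-3)
  expect_equal(clf$bias, 0, tolerance = 1e-3)
  # 2-D: perpendicular bisector of (2,0)-(0,0) is x1 = 1
  clf2 <- train_linear_svm(rbind(c(2, 0)), rbind(c(0, 0)), cost = 1e6)
  expect_equal(s_value(clf2, c(2, 0)), 1, tolerance = 1e-3)
  expect_equal(s_value(clf2, c(1, 5)), 0, tolerance = 1e-3)
  expect_error(train_linear_svm(matrix(1), matrix(NA_real_)),
               class = "perisacc_invalid_input")
  expect_error(train_linear_svm(matrix(1, 1, 2), matrix(1, 1, 3)),
               class = "perisacc_invalid_input")
})

test_that("identical classes yield zero s-values and chance AUC", {
  set.seed(1)
  x <- matrix(rnorm(10), 2, 5)
  clf <- train_linear_svm(x, x, cost = 1e3)
  s <- s_value(clf, x)
  expect_true(all(s == 0))
  expect_equal(roc_auc(s, s)$auc, 0.5)
})

test_that("s-values are plane geometry", {
  clf <- structure(list(weights = c(3, 4), bias = 0),
                   class = "linear_classifier")
  expect_equal(s_value(clf, c(3, 4)), 5)                 # (9+16)/5
  expect_equal(s_value(clf, c(4, -3)), 0)                # on the plane
  x <- c(1.2, -0.7)
  expect_equal(s_value(clf, -x), -s_value(clf, x))       # antisymmetry
  expect_error(s_value(clf, c(1, 2, 3)), class = "perisacc_invalid_input")
})

test_that("leave-one-out s-values equal hand geometry and an independent
           solver", {
  # 1-D: hold out +1 -> boundary midway between +2 and -1 at +0.5
  pos <- matrix(c(1, 2)); neg <- matrix(c(-1, -2))
  tab <- loo_svalues(pos, neg, cost = 1e6)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$s[tab$true_class == "pos"][1], 0.5, tolerance = 1e-3)
  # cross-solver: explicit per-k retraining with kernlab
  set.seed(42)
  for (r in 1:5) {
    n <- sample(3:5, 1)
    pos <- matrix(rnorm(n * 4, 1), n); neg <- matrix(rnorm(n * 4, -1), n)
    rownames(pos) <- paste0("p", 1:n); rownames(neg) <- paste0("n", 1:n)
    tab <- loo_svalues(pos, neg, cost = 10)
    for (i in 1:n) {
      s_or <- kernlab_svalues(pos[-i, , drop = FALSE], neg, 10,
                              rbind(pos[i, ]))
      expect_equal(tab$s[tab$trial_id == paste0("p", i)], s_or,
                   tolerance = 0.02)
    }
  }
})

test_that("ROC/AUC matches exhaustive pair counting and has a valid
           threshold sweep", {
  r <- roc_auc(c(0.9, 0.2), c(0.5, 0.1))
  expect_equal(r$auc, 0.75)                   # 3 of 4 pairs
  expect_equal(roc_auc(1:3, -(1:3))$auc, 1)
  expect_equal(roc_auc(c(1, 2), c(1, 2))$auc, 0.5)
  # curve: monotone, endpoints (0,0) and (1,1)
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_equal(r$curve$tpr[1], 0); expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_error(roc_auc(numeric(0), 1), class = "perisacc_insufficient_data")
  # AUC invariant under strictly increasing transforms
  set.seed(2)
  sp <- rnorm(20); sn <- rnorm(15)
  expect_equal(roc_auc(sp, sn)$auc, roc_auc(exp(sp), exp(sn))$auc)
  expect_equal(roc_auc(sp, sn)$auc,
               roc_auc(atan(sp / 3), atan(sn / 3))$auc)
})

test_that("percent correct: hyperplane criterion vs optimal threshold", {
  expect_equal(percent_correct(c(1, 2), c(-1, -2), "svm"), 1)
  expect_equal(percent_correct(c(1, 2), c(-1, -2), "optimal"), 1)
  expect_equal(percent_correct(c(0.9, 0.2), c(0.5, 0.1), "optimal"), 0.75)
  set.seed(3)
  for (r in 1:20) {
    sp <- rnorm(8); sn <- rnorm(8, -0.5)
    expect_gte(percent_correct(sp, sn, "optimal"),
               percent_correct(sp, sn, "svm"))
  }
})

test_that("mean-amplitude baseline scores epochs by their mean", {
  pos <- rbind(rep(1, 4), rep(0.8, 4))
  neg <- rbind(rep(0.2, 4), rep(0.4, 4))
  expect_equal(amplitude_auc(pos, neg)$auc, 1)
  expect_equal(amplitude_auc(pos, pos)$auc, 0.5)
  # shape-only control: all amplitude scores collapse to 0
  expect_equal(amplitude_auc(shape_only(pos), shape_only(neg))$auc, 0.5)
})

test_that("shape-only subtraction removes each epoch's mean", {
  expect_equal(shape_only(rbind(c(1, 2, 3))), rbind(c(-1, 0, 1)))
  expect_equal(shape_only(rbind(rep(4, 5))), rbind(rep(0, 5)))
  z <- rbind(c(-1, 0, 1))
  expect_equal(shape_only(z), z)
})

test_that("channel pooling sums per-trial s-values", {
  t1 <- data.frame(trial_id = c("a", "b"), true_class = c("pos", "neg"),
                   s = c(2, 0))
  t2 <- data.frame(trial_id = c("a", "b"), true_class = c("pos", "neg"),
                   s = c(1, -1))
  expect_equal(pool_channels(list(t1, t2))$auc, 1)   # pooled +3 vs -1
  expect_equal(pool_channels(list(t1))$auc,
               roc_auc(2, 0)$auc)
  tz <- t1; tz$s <- 0
  expect_equal(pool_channels(list(t1, tz))$auc, pool_channels(list(t1))$auc)
  t3 <- data.frame(trial_id = c("a", "c"), true_class = c("pos", "neg"),
                   s = c(1, 0))
  expect_error(pool_channels(list(t1, t3)),
               class = "perisacc_misaligned_channels")
})

test_that("sequential addition stops when pooling hurts", {
  mk <- function(sp, sn) data.frame(
    trial_id = c("a", "b", "c", "d"),
    true_class = c("pos", "pos", "neg", "neg"), s = c(sp, sn))
  good <- mk(c(10, 9), c(0, 1))    # AUC 1
  bad <- mk(c(-20, 0), c(0, 0))    # AUC 0.25, ruins the pool
  res <- sequential_optimal(list(good, bad))
  expect_equal(res$channels, 1)
  expect_equal(res$auc, 1)
  # optimal prefix is never worse than pooling everything
  expect_gte(res$auc, res$prefix_auc[length(res$prefix_auc)])
  one <- sequential_optimal(list(good))
  expect_equal(one$channels, 1)
  expect_equal(one$auc, 1)
})
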