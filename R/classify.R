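# Linear max-margin classification of LFP epochs, signed-distance
# (s-value) scoring under leave-one-out cross-validation, criterion-free
# ROC/AUC, percent-correct criteria, the mean-amplitude baseline, and
# channel pooling with sequential-addition optimization.

#' Train a soft-margin linear SVM on epoch matrices
#'
#' Solves the linear-kernel soft-margin QP (via libsvm) for the
#' maximum-margin hyperplane between the positive (saccade) and negative
#' (fixation) epochs, each row a feature vector of unweighted 1 ms
#' samples. The returned weights are oriented so positive decision values
#' lie on the positive-class side. If the two classes are numerically
#' indistinguishable the optimum has zero weights; `s_value()` then
#' scores every point as 0 (on the hyperplane).
#'
#' @param pos,neg epoch matrices (rows = trials) for the two classes.
#' @param cost soft-margin cost C; large values approach the hard margin.
#' @param meta optional list of provenance (channel, tau_train, classes).
#' @return object of class `linear_classifier` with `weights`, `bias`,
#'   `meta`.
#' @export
train_linear_svm <- function(pos, neg, cost = 1, meta = list()) {
  pos <- rbind(pos); neg <- rbind(neg)
  if (nrow(pos) < 1 || nrow(neg) < 1)
    ps_error("each class needs at least one example",
             "perisacc_insufficient_class")
  if (ncol(pos) != ncol(neg))
    ps_error("feature dimensions differ between classes",
             "perisacc_invalid_input")
  x <- rbind(pos, neg)
  if (!all(is.finite(x)))
    ps_error("non-finite feature values", "perisacc_invalid_input")
  y <- factor(rep(c("pos", "neg"), c(nrow(pos), nrow(neg))),
              levels = c("pos", "neg"))
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  if (fit$levels[fit$labels[1]] != "pos") { # libsvm orients by first seen
    w <- -w; b <- -b
  }
  structure(list(weights = w, bias = b, cost = cost, meta = meta),
            class = "linear_classifier")
}

#' Signed distance of feature vectors to the separating hyperplane
#'
#' s = (w . x + b) / ||w||, in feature-space units; positive s lies on
#' the positive-class (saccade) side. Zero-weight classifiers (identical
#' classes) score everything 0.
#'
#' @param clf a `linear_classifier`.
#' @param x feature vector, or matrix with one vector per row.
#' @return numeric s-value(s).
#' @export
s_value <- function(clf, x) {
  x <- rbind(x)
  if (ncol(x) != length(clf$weights))
    ps_error("feature dimension mismatch", "perisacc_invalid_input")
  nw <- sqrt(sum(clf$weights^2))
  if (nw == 0) return(rep(0, nrow(x)))
  as.numeric(x %*% clf$weights + clf$bias) / nw
}

#' Leave-one-out s-values for two epoch classes
#'
#' For every trial k (of either class) an SVM is trained with that trial
#' removed and the held-out trial is scored by its signed distance to the
#' resulting hyperplane. Trials present in both classes (e.g. a trial
#' contributing its peri-saccadic epoch to the positive class and its
#' fixation epoch to the negative class) are removed from both sides when
#' held out, so no fold ever sees any epoch of the test trial.
#'
#' @param pos,neg epoch matrices; rownames are trial ids.
#' @param cost soft-margin cost.
#' @return data.frame (trial_id, true_class, s) of class `svalue_table`.
#' @export
loo_svalues <- function(pos, neg, cost = 1) {
  pos <- rbind(pos); neg <- rbind(neg)
  if (nrow(pos) < 2 || nrow(neg) < 2)
    ps_error("leave-one-out needs >= 2 examples per class",
             "perisacc_insufficient_class")
  idp <- rownames(pos) %||% paste0("p", seq_len(nrow(pos)))
  idn <- rownames(neg) %||% paste0("n", seq_len(nrow(neg)))
  score_one <- function(id, x, own) {
    p <- pos[idp != id, , drop = FALSE]
    n <- neg[idn != id, , drop = FALSE]
    if (nrow(p) < 1 || nrow(n) < 1)
      ps_error("a class is empty after holding out a trial",
               "perisacc_insufficient_class")
    s_value(train_linear_svm(p, n, cost = cost), x)
  }
  rows <- c(
    lapply(seq_len(nrow(pos)), function(i)
      data.frame(trial_id = idp[i], true_class = "pos",
                 s = score_one(idp[i], pos[i, ], "pos"))),
    lapply(seq_len(nrow(neg)), function(i)
      data.frame(trial_id = idn[i], true_class = "neg",
                 s = score_one(idn[i], neg[i, ], "neg")))
  )
  structure(do.call(rbind, rows), class = c("svalue_table", "data.frame"))
}

#' ROC curve and AUC from positive- and negative-class scores
#'
#' The threshold sweeps over all distinct scores (midpoints between
#' neighbors, plus +/- Inf), recording TPR and FPR at each; the AUC equals
#' the probability that a random positive score exceeds a random negative
#' one, ties counting 1/2 (computed exactly by the rank-sum pair
#' statistic, which the trapezoidal area under the swept curve matches).
#'
#' @param s_pos,s_neg numeric score vectors.
#' @return object of class `roc_curve`: data.frame `curve` (threshold,
#'   tpr, fpr) and scalar `auc`.
#' @export
roc_auc <- function(s_pos, s_neg) {
  if (length(s_pos) == 0 || length(s_neg) == 0)
    ps_error("both score sets must be non-empty",
             "perisacc_insufficient_data")
  all <- sort(unique(c(s_pos, s_neg)))
  thr <- c(Inf, rev(if (length(all) > 1)
    (all[-1] + all[-length(all)]) / 2 else all[1]), -Inf)
  curve <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(s_pos > t), numeric(1)),
    fpr = vapply(thr, function(t) mean(s_neg > t), numeric(1))
  )
  np <- length(s_pos); nn <- length(s_neg)
  r <- rank(c(s_pos, s_neg), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  structure(list(curve = curve, auc = auc,
                 n_pos = np, n_neg = nn), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      x$n_pos, " pos, ", x$n_neg, " neg)\n", sep = "")
  invisible(x)
}

#' Percent correct under the SVM or the optimal criterion
#'
#' `mode = "svm"` classifies by the hyperplane itself (s > 0 is positive).
#' `mode = "optimal"` scans all thresholds and reports the best achievable
#' accuracy under equal false-positive and false-negative costs; it can
#' never be below the SVM criterion's accuracy.
#'
#' @param s_pos,s_neg numeric score vectors.
#' @param mode `"svm"` or `"optimal"`.
#' @return achieved fraction correct in \[0, 1\].
#' @export
percent_correct <- function(s_pos, s_neg, mode = c("svm", "optimal")) {
  mode <- match.arg(mode)
  if (length(s_pos) == 0 || length(s_neg) == 0)
    ps_error("both score sets must be non-empty",
             "perisacc_insufficient_data")
  acc <- function(t)
    (sum(s_pos > t) + sum(s_neg <= t)) / (length(s_pos) + length(s_neg))
  if (mode == "svm") return(acc(0))
  all <- sort(unique(c(s_pos, s_neg)))
  cand <- c(-Inf, if (length(all) > 1)
    (all[-1] + all[-length(all)]) / 2 else NULL, all, Inf, 0)
  max(vapply(cand, acc, numeric(1)))
}

#' Mean-amplitude baseline classifier
#'
#' Scores each epoch by the mean of its samples and sweeps a threshold
#' across the two amplitude distributions -- the simple baseline against
#' which the 100-dimensional shape classifier is compared.
#'
#' @param pos,neg epoch matrices.
#' @return a `roc_curve`.
#' @export
amplitude_auc <- function(pos, neg) {
  roc_auc(rowMeans(rbind(pos)), rowMeans(rbind(neg)))
}

#' Remove each epoch's mean (shape-only control)
#'
#' @param epochs epoch matrix.
#' @return matrix of zero-mean rows.
#' @export
shape_only <- function(epochs) {
  epochs <- rbind(epochs)
  sweep(epochs, 1, rowMeans(epochs))
}

#' Pool s-values across channels and build an overall ROC
#'
#' Each trial's pooled score is the sum of its per-channel s-values; the
#' ROC is then computed over pooled positive and negative scores. With
#' `method = "concat"` the per-channel s-values are instead concatenated
#' into pooled histograms (one entry per trial per channel).
#'
#' @param tables list of `svalue_table`s, one per channel, covering the
#'   same trials.
#' @param method `"sum"` (default, one score per trial) or `"concat"`.
#' @return a `roc_curve`.
#' @export
pool_channels <- function(tables, method = c("sum", "concat")) {
  method <- match.arg(method)
  key <- function(t) paste(t$trial_id, t$true_class)
  k0 <- key(tables[[1]])
  for (t in tables)
    if (!identical(sort(key(t)), sort(k0)))
      ps_error("channels cover different trial sets",
               "perisacc_misaligned_channels")
  if (method == "concat") {
    s <- do.call(rbind, tables)
    return(roc_auc(s$s[s$true_class == "pos"], s$s[s$true_class == "neg"]))
  }
  base <- tables[[1]][order(k0), ]
  pooled <- rowSums(vapply(tables, function(t) t$s[order(key(t))],
                           numeric(nrow(base))))
  roc_auc(pooled[base$true_class == "pos"],
          pooled[base$true_class == "neg"])
}

#' Optimal channel combination by sequential addition
#'
#' Channels are ranked by single-channel AUC (descending); pooled AUC is
#' evaluated for every prefix of the ranking, and the prefix with the
#' highest pooled AUC is the "optimal combination".
#'
#' @param tables list of per-channel `svalue_table`s (named by channel).
#' @return list with `channels` (ranked indices of the optimal prefix),
#'   `auc`, and `prefix_auc` (AUC of every prefix).
#' @export
sequential_optimal <- function(tables) {
  if (length(tables) < 1)
    ps_error("need at least one channel", "perisacc_insufficient_data")
  single <- vapply(tables, function(t)
    roc_auc(t$s[t$true_class == "pos"], t$s[t$true_class == "neg"])$auc,
    numeric(1))
  ord <- order(single, decreasing = TRUE)
  prefix_auc <- vapply(seq_along(ord), function(k)
    pool_channels(tables[ord[seq_len(k)]])$auc, numeric(1))
  best <- which.max(prefix_auc)
  list(channels = ord[seq_len(best)], auc = prefix_auc[best],
       prefix_auc = prefix_auc, ranking = ord, single_auc = single)
}
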