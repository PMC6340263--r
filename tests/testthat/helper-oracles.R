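# Independent oracles and small fixtures, built in code.

# AUC by exhaustive pair counting: P(s_pos > s_neg), ties 1/2.
auc_pair_oracle <- function(s_pos, s_neg) {
  tot <- 0
  for (p in s_pos) for (n in s_neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(s_pos) * length(s_neg))
}

# s-values via an independent QP solver (kernlab), oriented to match.
kernlab_svalues <- function(pos, neg, cost, x) {
  y <- factor(rep(c("p", "n"), c(nrow(pos), nrow(neg))),
              levels = c("p", "n"))
  k <- NULL
  invisible(utils::capture.output(
    k <- kernlab::ksvm(x = rbind(pos, neg), y = y, type = "C-svc",
                       kernel = "vanilladot", C = cost, scaled = FALSE)))
  w <- as.numeric(t(unlist(kernlab::coef(k))) %*% kernlab::xmatrix(k)[[1]])
  dec <- as.numeric(kernlab::predict(k, x, type = "decision"))
  s <- dec / sqrt(sum(w^2))
  # orient so the positive class scores positive on separated data
  if (mean(as.numeric(kernlab::predict(k, pos, type = "decision"))) <
      mean(as.numeric(kernlab::predict(k, neg, type = "decision")))) s <- -s
  s
}

# Butterworth low-pass magnitude response at frequency f (Hz), one pass.
butter_gain <- function(bf, f, rate) {
  z <- exp(-1i * 2 * pi * f / rate)
  Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
        sum(bf$a * z^(seq_along(bf$a) - 1)))
}

# Small high-SNR session shared across tests (lazily built, then cached).
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(trials_per_direction = 8, n_channels = 3,
                          seed = 7)
      g <- gen_trialset(cfg)
      cache <<- list(cfg = cfg, truth = g$truth,
                     trials = normalize_trialset(g$trials))
    }
    cache
  }
})
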