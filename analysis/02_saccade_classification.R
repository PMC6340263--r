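#!/usr/bin/env Rscript
# Classify saccade vs fixation epochs, per channel and saccade direction.
#
# For each channel and direction: leave-one-out s-values for the tau = 25
# peri-saccadic window against the post-saccadic fixation window
# (tau = 250), ROC/AUC, percent correct under the hyperplane and optimal
# criteria, and the mean-amplitude baseline. Also pools channels by
# summed s-values with sequential-addition optimization.

suppressPackageStartupMessages(library(perisacc))
trials <- read_container("results/session.rds")
events <- read.csv("results/events_detected.csv")

rows <- list(); tables <- list()
for (ch in seq_len(dim(trials$lfp)[2])) {
  for (d in sort(unique(events$direction_deg))) {
    ids <- events$trial_id[events$direction_deg == d]
    pos <- epoch_matrix(trials, ch, window_spec(25), events, ids)
    neg <- epoch_matrix(trials, ch, window_spec(250), events, ids)
    sv <- loo_svalues(pos, neg)
    sp <- sv$s[sv$true_class == "pos"]; sn <- sv$s[sv$true_class == "neg"]
    rows[[paste(ch, d)]] <- data.frame(
      channel = ch, direction = d, tau = 25, window_length = 100,
      auc = roc_auc(sp, sn)$auc,
      pct_svm = percent_correct(sp, sn, "svm"),
      pct_opt = percent_correct(sp, sn, "optimal"),
      amplitude_auc = amplitude_auc(pos, neg)$auc,
      n_pos = length(sp), n_neg = length(sn))
    tables[[paste(ch, d)]] <- sv
  }
}
cls <- do.call(rbind, rows)
write.csv(cls, "results/classification.csv", row.names = FALSE)

message(sprintf(
  "Mean saccade/fixation AUC %.3f across %d channel x direction cells; %.1f%%
 of cells exceed 0.9. The mean-amplitude baseline reaches only %.3f,
 so classification rides on LFP shape.",
  mean(cls$auc), nrow(cls), 100 * mean(cls$auc > 0.9),
  mean(cls$amplitude_auc)))

pool <- do.call(rbind, lapply(sort(unique(events$direction_deg)), function(d) {
  chans <- lapply(seq_len(dim(trials$lfp)[2]),
                  function(ch) tables[[paste(ch, d)]])
  so <- sequential_optimal(chans)
  data.frame(direction = d, best_single_auc = max(so$single_auc),
             all_channel_pool_auc = so$prefix_auc[length(so$prefix_auc)],
             optimal_auc = so$auc, optimal_n_channels = length(so$channels))
}))
write.csv(pool, "results/channel_pooling.csv", row.names = FALSE)
message(sprintf(
  "Optimal channel combinations use %.1f channels on average and reach AUC %.3f.",
  mean(pool$optimal_n_channels), mean(pool$optimal_auc)))
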