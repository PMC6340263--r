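# Persistent trial container, configuration, and the end-to-end pipeline.
#
# The container is a single versioned RDS file holding the logical groups
# lfp / eye / events / meta (an array-heavy, attribute-rich bundle), with
# the events table optionally duplicated as a plain CSV for inspection.

CONTAINER_VERSION <- 1L

#' Write a trial set to a container file
#'
#' @param trials a `trial_set`.
#' @param path output file path (`.rds`).
#' @param events_csv optional path for a standalone events CSV copy.
#' @return `path`, invisibly.
#' @export
write_container <- function(trials, path, events_csv = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  obj <- list(format = "perisacc-container",
              version = CONTAINER_VERSION,
              lfp = trials$lfp, eye = trials$eye,
              events = trials$events,
              meta = list(time = trials$time,
                          sample_rate = trials$sample_rate,
                          sample_rate_eye = trials$sample_rate_eye,
                          normalized = trials$normalized,
                          norm_stats = trials$norm_stats,
                          cfg = trials$cfg))
  saveRDS(obj, path)
  if (!is.null(events_csv))
    utils::write.csv(trials$events, events_csv, row.names = FALSE)
  invisible(path)
}

#' Read a trial set back from a container file
#'
#' @param path container file written by [write_container()].
#' @return a `trial_set`.
#' @export
read_container <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    ps_error(sprintf("cannot read container '%s': %s", path,
                     conditionMessage(e)), "perisacc_format"))
  if (!identical(obj$format, "perisacc-container"))
    ps_error("not a perisacc container file", "perisacc_format")
  if (!identical(obj$version, CONTAINER_VERSION))
    ps_error(sprintf("container version %s; this build reads version %d",
                     obj$version %||% "<missing>", CONTAINER_VERSION),
             "perisacc_format")
  for (grp in c("lfp", "eye", "events", "meta"))
    if (is.null(obj[[grp]]))
      ps_error(sprintf("container is missing the '%s' group", grp),
               "perisacc_format")
  structure(list(lfp = obj$lfp, eye = obj$eye, time = obj$meta$time,
                 events = obj$events,
                 sample_rate = obj$meta$sample_rate,
                 sample_rate_eye = obj$meta$sample_rate_eye,
                 normalized = obj$meta$normalized,
                 norm_stats = obj$meta$norm_stats,
                 cfg = obj$meta$cfg),
            class = "trial_set")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror [synth_config()] plus optional
#'   `pipeline` settings (see [run_pipeline()]).
#' @return nested list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Run the full analysis pipeline on one synthetic session
#'
#' Stages: simulate (generator), detect (velocity-threshold events),
#' classify (per-direction saccade-vs-fixation LOO AUC per channel, with
#' SVM/optimal percent correct and the mean-amplitude baseline), sweep
#' (timing votes and RMS at the configured training centers), direction
#' (one-vs-rest AUCs, 12-way decoding, circular estimates and angular
#' error summary). Every stochastic stage consumes a named sub-seed
#' derived from the master seed, so results are reproducible end to end.
#'
#' @param config nested list: `synth` (arguments to [synth_config()]) and
#'   optional `pipeline` list with `channels`, `directions`, `tau_train`,
#'   `cost`, `k_folds`, `use_detected_events` (default TRUE; FALSE
#'   consumes ground-truth events directly), and `stages` (character
#'   subset of c("classify","sweep","direction")).
#' @param seed master seed; overrides `config$synth$seed`.
#' @param out_dir optional directory: result tables are written as CSVs
#'   and a manifest as JSON.
#' @return list of result tables plus the manifest.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  sargs <- config$synth %||% list()
  sargs$seed <- derive_seed(seed, "simulate")
  cfg <- do.call(synth_config, sargs)
  pl <- utils::modifyList(list(
    channels = seq_len(min(cfg$n_channels, 4L)),
    directions = cfg$directions,
    tau_train = 25, cost = 1, k_folds = 10L,
    use_detected_events = TRUE,
    stages = c("classify", "sweep", "direction")
  ), config$pipeline %||% list())

  gen <- gen_trialset(cfg)
  trials <- normalize_trialset(gen$trials)
  events <- if (pl$use_detected_events) detect_events(trials)
            else gen$truth$events

  res <- list(truth = gen$truth$events, events = events)

  if ("classify" %in% pl$stages) {
    tab <- list()
    for (ch in pl$channels) for (d in pl$directions) {
      ids <- events$trial_id[events$direction_deg == d]
      pos <- epoch_matrix(trials, ch, window_spec(25), events, ids)
      neg <- epoch_matrix(trials, ch, window_spec(250), events, ids)
      sv <- loo_svalues(pos, neg, cost = pl$cost)
      sp <- sv$s[sv$true_class == "pos"]; sn <- sv$s[sv$true_class == "neg"]
      tab[[paste(ch, d)]] <- data.frame(
        channel = ch, direction = d, tau = 25, window_length = 100,
        auc = roc_auc(sp, sn)$auc,
        pct_svm = percent_correct(sp, sn, "svm"),
        pct_opt = percent_correct(sp, sn, "optimal"),
        amplitude_auc = amplitude_auc(pos, neg)$auc,
        n_pos = length(sp), n_neg = length(sn))
    }
    res$classify <- do.call(rbind, tab)
  }

  if ("sweep" %in% pl$stages) {
    sw <- sweep_channels(trials, pl$channels, direction = pl$directions[1],
                         tau_train = pl$tau_train, cost = pl$cost,
                         events = events)
    res$sweep <- sw$per_channel
    res$sweep_rms_curve <- sw$rms_curve
  }

  if ("direction" %in% pl$stages) {
    ovr <- do.call(rbind, lapply(pl$channels, function(ch)
      do.call(rbind, lapply(pl$directions, function(d)
        data.frame(channel = ch, direction = d,
                   ovr_auc = one_vs_rest_auc(trials, ch, d,
                                             cost = pl$cost,
                                             events = events)$auc)))))
    mw <- do.call(rbind, lapply(pl$channels, function(ch)
      cbind(channel = ch,
            multiway_classify(trials, ch, k_folds = pl$k_folds,
                              cost = pl$cost,
                              seed = derive_seed(seed, "folds"),
                              events = events))))
    est <- do.call(rbind, lapply(split(mw, mw$true_deg), function(d)
      data.frame(direction = d$true_deg[1],
                 estimate_deg = circular_mean(d$predicted_deg))))
    res$direction_ovr <- ovr
    res$direction_votes <- mw
    res$direction_estimates <- est
    res$direction_errors <- direction_error_stats(est$estimate_deg,
                                                  est$direction)
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("perisacc")),
    r_version = R.version.string,
    master_seed = seed,
    sub_seeds = list(simulate = derive_seed(seed, "simulate"),
                     folds = derive_seed(seed, "folds")),
    config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res))
      if (is.data.frame(res[[nm]]))
        utils::write.csv(res[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    jsonlite::write_json(res$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}
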