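# End-to-end pipeline: preprocess -> connectivity -> per-fold feature
# extraction and graph-classifier training -> cross-validated metrics with
# bootstrap confidence intervals and Mann-Whitney validation of the fused
# connectivity.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one flat list. Defaults are
#' the package's standard operating point: 0.5-60 Hz bandpass, 128 Hz,
#' 5-s segments, Welch windows of 128 samples with 50% overlap, a
#' per-segment small-worldness threshold search on the 0.30-0.70 grid,
#' LSTM/CNN extractors trained for 10 epochs (batch 32), a GCN trained for
#' 100 epochs (batch 64, learning rate 1e-3), five-fold cross-validation
#' and 1000 bootstrap resamples at the 95% level.
#'
#' @param low,high Bandpass edges (Hz).
#' @param fs Working sampling rate (Hz).
#' @param window_s Segment length (s).
#' @param welch_n,welch_overlap Welch window length (samples) and overlap.
#' @param threshold_mode "per-segment" (each segment's own fused matrix is
#'   searched) or "global" (one threshold from the training-fold average).
#' @param n_random Random reference graphs per small-worldness evaluation.
#' @param lstm_hidden,extractor_fc LSTM hidden width and FC width of both
#'   extractors.
#' @param extractor_epochs,extractor_batch,extractor_lr Extractor training.
#' @param gcn_epochs,gcn_batch,gcn_lr GCN training.
#' @param dropout Dropout probability used throughout.
#' @param k_folds Cross-validation folds.
#' @param cv_unit "segment" or "subject" fold assignment.
#' @param n_boot,ci_level Bootstrap settings.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(low = 0.5, high = 60, fs = 128, window_s = 5,
                            welch_n = 128, welch_overlap = 0.5,
                            threshold_mode = "per-segment", n_random = 20,
                            lstm_hidden = 128, extractor_fc = 64,
                            extractor_epochs = 10, extractor_batch = 32,
                            extractor_lr = 1e-3, gcn_epochs = 100,
                            gcn_batch = 64, gcn_lr = 1e-3, dropout = 0.5,
                            k_folds = 5, cv_unit = "segment", n_boot = 1000,
                            ci_level = 0.95, seed = 1L) {
  threshold_mode <- match.arg(threshold_mode, c("per-segment", "global"))
  cv_unit <- match.arg(cv_unit, c("segment", "subject"))
  structure(list(low = low, high = high, fs = fs, window_s = window_s,
                 welch_n = welch_n, welch_overlap = welch_overlap,
                 threshold_mode = threshold_mode, n_random = n_random,
                 lstm_hidden = lstm_hidden, extractor_fc = extractor_fc,
                 extractor_epochs = extractor_epochs,
                 extractor_batch = extractor_batch,
                 extractor_lr = extractor_lr, gcn_epochs = gcn_epochs,
                 gcn_batch = gcn_batch, gcn_lr = gcn_lr, dropout = dropout,
                 k_folds = k_folds, cv_unit = cv_unit, n_boot = n_boot,
                 ci_level = ci_level, seed = as.integer(seed)),
            class = c("pipeline_config", "list"))
}

#' Preprocess a cohort into labeled segments
#'
#' @param cohort List with `recording`, `label`, `subject_id` per subject
#'   (as from [generate_cohort()] or [read_cohort()]).
#' @param config A [pipeline_config()].
#' @return List of labeled [eeg_segment()]s.
#' @export
segments_from_cohort <- function(cohort, config = pipeline_config()) {
  out <- list()
  for (s in cohort) {
    segs <- preprocess_recording(s$recording, low = config$low,
                                 high = config$high,
                                 target_fs = config$fs,
                                 window_s = config$window_s,
                                 label = s$label, subject_id = s$subject_id)
    out <- c(out, segs)
  }
  out
}

#' Fused connectivity and binarized graphs for a list of segments
#'
#' Computes each segment's PLI, COH and fused matrix, then binarizes with
#' the per-segment small-worldness threshold search (the "global" mode is
#' resolved later, per training fold, in [run_pipeline()]).
#'
#' @param segments List of [eeg_segment()]s.
#' @param config A [pipeline_config()].
#' @return List with one element per segment: `pcoh`, `adjacency`,
#'   `threshold`, `label`, `subject_id`.
#' @export
connectivity_graphs <- function(segments, config = pipeline_config()) {
  lapply(segments, function(s) {
    pc <- segment_pcoh(s, n_window = config$welch_n,
                       overlap = config$welch_overlap,
                       band = c(config$low, config$high))
    bw <- suppressWarnings(
      binarize_smallworld(pc, n_random = config$n_random,
                          seed = config$seed))
    list(pcoh = pc, adjacency = bw$adjacency,
         threshold = bw$threshold_used, label = s$label,
         subject_id = s$subject_id)
  })
}

extractor_cfg_from <- function(config, seed) {
  extractor_config(epochs = config$extractor_epochs,
                   batch_size = config$extractor_batch,
                   lr = config$extractor_lr, dropout = config$dropout,
                   hidden = config$lstm_hidden, fc_size = config$extractor_fc,
                   seed = seed)
}

#' Run the full cross-validated pipeline
#'
#' Stages: preprocess -> fused connectivity + binarization -> for each
#' fold, train the LSTM/CNN extractors and the graph classifier on the
#' training portion only, predict the held-out fold -> metrics with
#' bootstrap confidence intervals, Mann-Whitney U on pooled fused
#' connectivity entries, and group-average connectivity matrices. When
#' `out_dir` is given, writes a metrics TSV (one row per fold plus the
#' average), per-epoch training curves, the resolved configuration,
#' `.node`/`.edge` exports of the group averages, and a stage-timing log
#' (`run.log`); stage progress is also emitted as messages.
#'
#' @param cohort Cohort list (from [generate_cohort()] or [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param permute_labels Permutation null control: when `TRUE`, segment
#'   labels are randomly permuted (seeded) after preprocessing, so any
#'   above-chance cross-validated accuracy would indicate leakage rather
#'   than signal.
#' @return List with `fold_metrics` (data frame), `predictions`,
#'   `mann_whitney`, `group_average`, `thresholds`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         permute_labels = FALSE) {
  log_lines <- character()
  stage_t0 <- proc.time()[3]
  log_stage <- function(fmt, ...) {
    line <- sprintf("[%7.1fs] %s", proc.time()[3] - stage_t0,
                    sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  segments <- segments_from_cohort(cohort, config)
  if (length(segments) < config$k_folds)
    stop("cohort yields fewer segments than folds")
  log_stage("preprocess: %d recordings -> %d segments", length(cohort),
            length(segments))
  labels <- vapply(segments, function(s) s$label, integer(1))
  if (permute_labels) {
    labels <- with_seed(derive_seed(config$seed, 77L), sample(labels))
    for (i in seq_along(segments)) segments[[i]]$label <- labels[i]
    log_stage("labels permuted for the null control")
  }
  subjects <- vapply(segments, function(s) s$subject_id, character(1))
  graphs <- connectivity_graphs(segments, config)
  log_stage("connectivity: %d fused matrices binarized (%s threshold)",
            length(graphs), config$threshold_mode)

  folds <- make_folds(labels, k = config$k_folds,
                      seed = derive_seed(config$seed, 11L),
                      subjects = if (config$cv_unit == "subject") subjects)
  for (fid in seq_len(config$k_folds)) {
    if (length(unique(labels[folds != fid])) < 2L)
      stop("fold ", fid, ": training portion lacks a class")
  }

  predictions <- integer(length(segments))
  fold_rows <- list()
  curves <- list()
  for (fid in seq_len(config$k_folds)) {
    tr <- which(folds != fid)
    te <- which(folds == fid)
    ecfg_t <- extractor_cfg_from(config, derive_seed(config$seed, 21L, fid))
    ecfg_f <- extractor_cfg_from(config, derive_seed(config$seed, 22L, fid))
    tmod <- train_time_extractor(segments[tr], ecfg_t)
    fmod <- train_freq_extractor(segments[tr], ecfg_f)

    adj_for <- function(idx) {
      if (config$threshold_mode == "per-segment")
        return(lapply(graphs[idx], `[[`, "adjacency"))
      avg <- group_average_connectivity(
        list(all = lapply(graphs[tr], `[[`, "pcoh")))$all
      th <- suppressWarnings(
        select_threshold(avg, n_random = config$n_random,
                         seed = config$seed)$chosen)
      lapply(graphs[idx], function(g) binarize(g$pcoh, th)$adjacency)
    }
    feat_of <- function(i)
      concat_features(time_features(segments[[i]], tmod),
                      freq_features(segments[[i]], fmod))
    ftr <- lapply(tr, feat_of)
    fte <- lapply(te, feat_of)
    # column-standardize node features with training-fold statistics
    stk <- do.call(rbind, ftr)
    mu <- colMeans(stk)
    sdv <- apply(stk, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    std <- function(X) sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    mk_samples <- function(idx, adjs, feats) {
      lapply(seq_along(idx), function(j) {
        i <- idx[j]
        graph_sample(adjs[[j]], std(feats[[j]]),
                     label = labels[i], subject_id = subjects[i])
      })
    }
    tr_samples <- mk_samples(tr, adj_for(tr), ftr)
    te_samples <- mk_samples(te, adj_for(te), fte)

    gcfg <- gcn_config(epochs = config$gcn_epochs,
                       batch_size = config$gcn_batch, lr = config$gcn_lr,
                       dropout = config$dropout,
                       seed = derive_seed(config$seed, 23L, fid))
    gmod <- gcn_train(tr_samples, gcfg, validation = te_samples)
    pred <- gcn_predict(gmod, te_samples)$predicted
    predictions[te] <- pred

    mets <- classification_metrics(confusion(pred, labels[te]))
    cis <- lapply(c(accuracy = "accuracy", recall = "recall",
                    precision = "precision"), function(m)
      tryCatch(bootstrap_ci(pred, labels[te], m, n_boot = config$n_boot,
                            level = config$ci_level,
                            seed = derive_seed(config$seed, 31L, fid)),
               error = function(e) list(lo = NA_real_, hi = NA_real_)))
    log_stage("fold %d: trained on %d, held out %d, accuracy %.3f", fid,
              length(tr), length(te), mets$accuracy)
    fold_rows[[fid]] <- data.frame(
      fold = fid, n = length(te),
      accuracy = mets$accuracy, accuracy_lo = cis$accuracy$lo,
      accuracy_hi = cis$accuracy$hi,
      recall = mets$recall, recall_lo = cis$recall$lo,
      recall_hi = cis$recall$hi,
      precision = mets$precision, precision_lo = cis$precision$lo,
      precision_hi = cis$precision$hi)
    curves[[fid]] <- cbind(fold = fid, gmod$history)
  }

  fold_metrics <- do.call(rbind, fold_rows)
  avg <- data.frame(fold = NA_integer_, n = sum(fold_metrics$n),
                    t(colMeans(fold_metrics[, -(1:2)], na.rm = TRUE)))
  fold_metrics <- rbind(fold_metrics, avg)

  by_group <- split(lapply(graphs, `[[`, "pcoh"), labels)
  names(by_group) <- paste0("label", names(by_group))
  mwu <- mann_whitney_connectivity(by_group[[1]], by_group[[2]])
  gavg <- group_average_connectivity(by_group)

  res <- list(fold_metrics = fold_metrics,
              predictions = data.frame(subject_id = subjects, fold = folds,
                                       label = labels,
                                       predicted = predictions),
              mann_whitney = mwu, group_average = gavg,
              thresholds = vapply(graphs, `[[`, numeric(1), "threshold"),
              curves = do.call(rbind, curves), config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(fold_metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$predictions,
                       file.path(out_dir, "predictions.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(res$curves, file.path(out_dir, "curves.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    write_config(config, file.path(out_dir, "config.txt"))
    for (g in names(gavg)) {
      write_connectivity_tsv(gavg[[g]],
                             file.path(out_dir, paste0("pcoh_", g, ".tsv")))
      export_brainnet(gavg[[g]], file.path(out_dir, paste0("pcoh_", g)))
    }
    writeLines(sprintf("mann_whitney_U\t%g\nmann_whitney_p\t%g",
                       mwu$U, mwu$p),
               file.path(out_dir, "mann_whitney.tsv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  res
}
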