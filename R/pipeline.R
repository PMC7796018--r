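#' End-to-end pipeline configuration
#'
#' @param out_dir directory for artifacts.
#' @param days_train,days_val,days_test whole-day split sizes (the split is
#'   by calendar day).
#' @param n_anomalies injections into the test days.
#' @param anomaly_kind `"subactivity"` or `"activity"`.
#' @param feature `"rsm"` (greedy trees per minute) or `"bos"` (linear trees
#'   over w-row chunks).
#' @param mode,tree,alpha,epochs,lr,batch training settings (see
#'   [training_config()]).
#' @param score_mode `"avg_parents"` or `"root"` (RSM only).
#' @param window_minutes window length; `w` rows per BOS chunk.
#' @param seed master seed; stage seeds are derived from it.
#' @param top_nodes,ngrams pattern-mining settings.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("raetrace_run_"),
                       days_train = 5, days_val = 0, days_test = 2,
                       n_anomalies = 10,
                       anomaly_kind = c("subactivity", "activity"),
                       feature = c("rsm", "bos"),
                       mode = "unsupervised", tree = "greedy", alpha = 0.2,
                       epochs = 3, lr = 0.01, batch = 20,
                       score_mode = "avg_parents",
                       window_minutes = 1, w = 25, seed = 1L,
                       top_nodes = 500, ngrams = c(2, 3)) {
  cfg <- list(out_dir = out_dir, days_train = days_train, days_val = days_val,
              days_test = days_test, n_anomalies = n_anomalies,
              anomaly_kind = match.arg(anomaly_kind),
              feature = match.arg(feature), mode = mode, tree = tree,
              alpha = alpha, epochs = epochs, lr = lr, batch = batch,
              score_mode = score_mode, window_minutes = window_minutes,
              w = w, seed = as.integer(seed), top_nodes = top_nodes,
              ngrams = ngrams)
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full detection pipeline
#'
#' Generates normal routine days, splits them by whole days into train /
#' test, injects anomalies into the test days, featurizes, trains the RAE,
#' scores the test windows, evaluates the ROC, mines n-gram patterns (greedy
#' trees only), and writes every artifact plus a reproducibility manifest to
#' `config$out_dir`: `train.txt`, `test.txt`, `truth.json`, `scores.csv`,
#' `roc.csv`, `patterns.csv`, `params.json`, `manifest.json`.
#'
#' @param config a [run_config()].
#' @param model routine model (default [default_aruba_model()]).
#' @return invisible list with the in-memory artifacts (`scores` data frame,
#'   `roc`, `patterns`, `params`, `paths`).
#' @export
run_pipeline <- function(config = run_config(), model = default_aruba_model()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reg <- model$registry
  seed <- config$seed
  n_train_days <- config$days_train + config$days_val

  train_log <- stage("generate", {
    generate_days(model, n_train_days, seed = seed)
  })
  test_log <- stage("generate", {
    generate_days(model, config$days_test, seed = seed + 1000L,
                  start_date = as.Date("2021-03-01") + n_train_days)
  })
  inj <- stage("inject", {
    if (config$anomaly_kind == "subactivity") {
      inject_subactivity_anomalies(test_log, n = config$n_anomalies,
                                   seed = seed + 2000L)
    } else {
      inject_activity_anomalies(test_log, n = config$n_anomalies,
                                seed = seed + 2000L, donor_log = train_log)
    }
  })
  paths <- list(train = file.path(config$out_dir, "train.txt"),
                test = file.path(config$out_dir, "test.txt"),
                truth = file.path(config$out_dir, "truth.json"),
                scores = file.path(config$out_dir, "scores.csv"),
                roc = file.path(config$out_dir, "roc.csv"),
                patterns = file.path(config$out_dir, "patterns.csv"),
                params = file.path(config$out_dir, "params.json"),
                manifest = file.path(config$out_dir, "manifest.json"))
  write_casas_log(train_log, paths$train)
  write_casas_log(inj$log, paths$test)
  write_truth(inj$records, paths$truth)

  train_chunks <- stage("featurize", {
    segment_windows(train_log, config$window_minutes, reg)
  })
  test_chunks <- stage("featurize", {
    segment_windows(inj$log, config$window_minutes, reg)
  })

  tcfg <- training_config(mode = config$mode, tree = config$tree,
                          alpha = config$alpha, epochs = config$epochs,
                          lr = config$lr, batch = config$batch,
                          seed = seed + 3000L)
  fit <- stage("train", {
    if (config$feature == "rsm") {
      tr <- rsm_leaf_matrices(train_chunks, reg)
      rae_train(tr$inputs, tcfg, labels = tr$labels, n = length(reg))
    } else {
      ch <- bos_chunk_matrices(train_chunks, config$w, reg)
      rae_train(lapply(ch$rows, t), tcfg, n = length(reg))
    }
  })
  save_params(fit, paths$params)

  scored <- stage("score", {
    if (config$feature == "rsm") {
      data.frame(window_start = test_chunks$start,
                 window_end = test_chunks$end,
                 score = score_windows_rsm(test_chunks, fit,
                                           config$score_mode, reg),
                 truth = windows_truth(test_chunks, inj$records))
    } else {
      ch <- bos_chunk_matrices(test_chunks, config$w, reg)
      wt <- windows_truth(test_chunks, inj$records)
      data.frame(window_start = ch$start, window_end = ch$end,
                 score = vapply(ch$rows, score_bos_chunk, 0, params = fit),
                 truth = vapply(ch$window_index, function(m) any(wt[m]), TRUE))
    }
  })
  roc <- stage("evaluate", roc_curve(scored$score, scored$truth))
  thr <- stats::median(scored$score[!scored$truth])
  scored$prediction <- threshold_scores(scored$score, thr)
  utils::write.csv(format_scores(scored), paths$scores, row.names = FALSE)
  utils::write.csv(cbind(roc$points, auc = roc$auc), paths$roc,
                   row.names = FALSE)

  pats <- NULL
  if (config$tree == "greedy" && config$feature == "rsm") {
    pats <- stage("patterns", {
      trees <- window_trees(train_chunks, fit, reg)
      top <- extract_top_nodes(trees, config$top_nodes)
      do.call(rbind, lapply(config$ngrams, ngram_patterns, top_nodes = top,
                            registry = reg))
    })
    utils::write.csv(pats, paths$patterns, row.names = FALSE)
  }

  manifest <- c(unclass(config),
                list(package_version = as.character(utils::packageVersion("raetrace")),
                     auc = roc$auc))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(scores = scored, roc = roc, patterns = pats, params = fit,
                 paths = paths, truth = inj$records))
}

format_scores <- function(scored) {
  data.frame(window_start = format(scored$window_start, "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"),
             window_end = format(scored$window_end, "%Y-%m-%d %H:%M:%S",
                                 tz = "UTC"),
             score = sprintf("%.10g", scored$score),
             truth = scored$truth, prediction = scored$prediction,
             stringsAsFactors = FALSE)
}
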