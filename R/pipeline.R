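# End-to-end pipeline: simulate -> extract -> build-trainset -> train ->
# classify -> evaluate, writing every artifact (plus the config and seed
# used) under one output directory.

pipeline_stages <- function() {
  c("simulate", "extract", "build-trainset", "train", "classify", "evaluate")
}

stage_deps <- function(stage, out_dir, need) {
  for (f in need) {
    if (!file.exists(file.path(out_dir, f)))
      stop(sprintf("stage '%s' needs missing artifact %s; run '%s' first",
                   stage, f, attr(need, "from")))
  }
}

#' Run the fall-detection pipeline
#'
#' Executes the requested stages in order against one output directory.
#' Every artifact is plain text; `run.json` records the configuration and
#' seed, so identical config + seed reproduce identical outputs.
#'
#' Stages: `simulate` (scripted protocol + manifest), `extract` (per-trial
#' feature files), `build-trainset` (two-fold split and labeled frames),
#' `train` (SVM model), `classify` (per-frame labels and trial decisions on
#' the held-out fold), `evaluate` (frame and trial metrics).
#'
#' @param config a `run_config` from [default_config()].
#' @param stages subset of the stage names, in any order.
#' @param out_dir output directory (created if needed).
#' @return Named list of stage results (invisibly where large); the
#'   `evaluate` entry holds `frame_report` and `trial_report`.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = pipeline_stages(), out_dir) {
  stopifnot(all(stages %in% pipeline_stages()))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  res <- list()
  cfgs <- feature_settings_from(config)
  jsonlite::write_json(unclass(config), file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage <- function(name, t0, what) {
    message(sprintf("[%s] %s (%.1f s)", name, what,
                    as.numeric(Sys.time()) - t0))
  }
  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    if (stage == "simulate") {
      proto <- generate_protocol(config$simulator$subjects,
                                 config$simulator$trials_per_adl,
                                 fs = config$sampling$fs, seed = config$seed,
                                 out_dir = file.path(out_dir, "traces"))
      log_stage(stage, t0, sprintf("%d traces", nrow(proto$manifest)))
      res$simulate <- proto$manifest
    } else if (stage == "extract") {
      mpath <- file.path(out_dir, "traces", "manifest.csv")
      stage_deps(stage, out_dir,
                 structure("traces/manifest.csv", from = "simulate"))
      manifest <- read_manifest(mpath)
      dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
      for (i in seq_len(nrow(manifest))) {
        f <- extract_features(read_trace(manifest$path[i],
                                         fs = config$sampling$fs), cfgs)
        write_features(f, file.path(out_dir, "features",
                                    basename(manifest$path[i])))
      }
      log_stage(stage, t0, sprintf("%d feature files", nrow(manifest)))
      res$extract <- TRUE
    } else if (stage == "build-trainset") {
      stage_deps(stage, out_dir,
                 structure("traces/manifest.csv", from = "simulate"))
      manifest <- read_manifest(file.path(out_dir, "traces", "manifest.csv"))
      halves <- split_cv(manifest, config$training$cv_mode,
                         seed = derive_seed(config$seed, 11))
      write_manifest(halves$train, file.path(out_dir, "train_manifest.csv"))
      write_manifest(halves$test, file.path(out_dir, "test_manifest.csv"))
      ts <- assemble_training_set(
        halves$train, select = config$training$select,
        params = config$training$params,
        seed = derive_seed(config$seed, 12), factor = config$training$factor,
        cfg = cfgs, features = load_feature_dir(out_dir, halves$train),
        fs = config$sampling$fs,
        negative_stride = config$training$negative_stride,
        positive_stride = config$training$positive_stride)
      write_frames(ts, file.path(out_dir, "trainset.csv"))
      log_stage(stage, t0, sprintf("%d frames", nrow(ts$X)))
      res$`build-trainset` <- ts
    } else if (stage == "train") {
      stage_deps(stage, out_dir,
                 structure("trainset.csv", from = "build-trainset"))
      ts <- read_frames(file.path(out_dir, "trainset.csv"))
      model <- svm_train(ts, gamma = config$training$gamma,
                         cost = config$training$cost,
                         scale = isTRUE(config$training$scale))
      save_model(model, file.path(out_dir, "model.txt"))
      log_stage(stage, t0, sprintf("%d support vectors",
                                   length(model$alphas)))
      res$train <- model
    } else if (stage == "classify") {
      stage_deps(stage, out_dir, structure("model.txt", from = "train"))
      stage_deps(stage, out_dir,
                 structure("test_manifest.csv", from = "build-trainset"))
      model <- load_model(file.path(out_dir, "model.txt"))
      test_mf <- read_manifest(file.path(out_dir, "test_manifest.csv"))
      feats <- load_feature_dir(out_dir, test_mf)
      pred <- classify_test_manifest(model, test_mf, feats, config, cfgs)
      utils::write.csv(pred, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE, quote = FALSE)
      log_stage(stage, t0, sprintf("%d trials", nrow(pred)))
      res$classify <- pred
    } else if (stage == "evaluate") {
      stage_deps(stage, out_dir,
                 structure("predictions.csv", from = "classify"))
      pred <- utils::read.csv(file.path(out_dir, "predictions.csv"))
      trial_report <- summarize_decisions(pred$predicted_fall,
                                          pred$is_fall, pred$adl_id)
      frame_report <- summarize_counts(tp = sum(pred$frames_tp),
                                       tn = sum(pred$frames_tn),
                                       fp = sum(pred$frames_fp),
                                       fn = sum(pred$frames_fn))
      out <- list(trial = report_as_list(trial_report),
                  frame = report_as_list(frame_report))
      jsonlite::write_json(out, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      log_stage(stage, t0,
                sprintf("trial accuracy %.2f%%, frame accuracy %.2f%%",
                        trial_report$accuracy, frame_report$accuracy))
      res$evaluate <- list(trial_report = trial_report,
                           frame_report = frame_report)
    }
  }
  invisible(res)
}

load_feature_dir <- function(out_dir, manifest) {
  fdir <- file.path(out_dir, "features")
  if (!dir.exists(fdir)) return(NULL)
  out <- list()
  for (p in manifest$path) {
    fp <- file.path(fdir, basename(p))
    if (file.exists(fp)) out[[p]] <- read_features(fp)
  }
  if (length(out)) out else NULL
}

# Per-trial classification of a test manifest: frame labels via the SVM,
# frame-level confusion against the 0.87-rule reference labels, and a
# trial-level fall decision (any detected event).
classify_test_manifest <- function(model, manifest, features, config, cfgs) {
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    f <- if (!is.null(features)) features[[row$path]] else NULL
    if (is.null(f))
      f <- extract_features(read_trace(row$path, fs = config$sampling$fs),
                            cfgs)
    pred <- classify_series(model, f, config$training$params)
    ref <- if (row$is_fall)
      label_trial(f, TRUE, fall_frame_threshold(f$cv_fast,
                                                config$training$factor))
    else label_trial(f, FALSE)
    ev <- frames_to_events(pred, config$sampling$fs,
                           config$events$min_on_s, config$events$merge_gap_s)
    rows[[i]] <- data.frame(
      path = row$path, subject = row$subject, adl_id = row$adl_id,
      trial = row$trial, is_fall = row$is_fall,
      predicted_fall = nrow(ev) > 0,
      frames_tp = sum(pred > 0 & ref > 0),
      frames_tn = sum(pred < 0 & ref < 0),
      frames_fp = sum(pred > 0 & ref < 0),
      frames_fn = sum(pred < 0 & ref > 0))
  }
  do.call(rbind, rows)
}

report_as_list <- function(rep) {
  out <- rep[c("tp", "tn", "fp", "fn", "sensitivity", "specificity",
               "accuracy")]
  if (!is.null(rep$per_adl)) out$per_adl <- rep$per_adl
  out
}
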