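#' Default run configuration
#'
#' Bundles every tunable of the pipeline. Values stated for the target
#' device and method (200 Hz, 12-bit, +/-2 g; 0.1 s window; 0.87 labeling
#' factor; 5 trials selected per ADL; gamma 5.3; C 4.7) are the defaults;
#' the rest (filter designs, event aggregation, simulator scale) are
#' package design choices, all overridable.
#'
#' @param ... named overrides of nested fields, dot-separated, e.g.
#'   `training.factor = 0.9`, `simulator.subjects = 2`.
#' @return A validated `run_config` (nested named list).
#' @export
default_config <- function(...) {
  cfg <- list(
    sampling = list(fs = 200, bits = 12, clip_g = 2),
    features = list(window_s = 0.1, hp_cutoff_hz = 0.3, hp_order = 4,
                    lp_cutoff_hz = 0.3, lp_order = 2),
    training = list(factor = 0.87, select = 5,
                    params = feature_params(), gamma = 5.3, cost = 4.7,
                    scale = FALSE, negative_stride = 1, positive_stride = 1,
                    cv_mode = "by_trial"),
    baseline = list(whisker = 1.5, rule = "any_param"),
    events = list(min_on_s = 0.05, merge_gap_s = 2.0, tol_s = 2.0),
    simulator = list(subjects = 10, trials_per_adl = 10, noise_sd = 0.02),
    seed = 1
  )
  apply_overrides(cfg, list(...))
}

apply_overrides <- function(cfg, overrides) {
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- overrides[[key]]
    else if (length(parts) == 2) cfg[[parts[1]]][[parts[2]]] <- overrides[[key]]
    else stop("override keys nest at most twice: ", key)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$sampling$fs > 0, cfg$features$window_s * cfg$sampling$fs >= 2,
            cfg$features$hp_cutoff_hz > 0,
            cfg$features$hp_cutoff_hz < cfg$sampling$fs / 2,
            cfg$features$lp_cutoff_hz > 0,
            cfg$features$lp_cutoff_hz < cfg$sampling$fs / 2,
            cfg$training$factor > 0, cfg$training$factor <= 1,
            cfg$training$select >= 1,
            all(cfg$training$params %in% feature_params()),
            cfg$training$gamma >= 0, cfg$training$cost > 0,
            cfg$events$min_on_s >= 0, cfg$events$merge_gap_s >= 0,
            cfg$events$tol_s >= 0,
            cfg$simulator$subjects >= 1, cfg$simulator$trials_per_adl >= 1)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (JSON)
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- unclass(default_config())
  for (sec in names(cfg)) {
    if (is.list(base[[sec]])) for (k in names(cfg[[sec]]))
      base[[sec]][[k]] <- cfg[[sec]][[k]]
    else base[[sec]] <- cfg[[sec]]
  }
  validate_config(base)
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

feature_settings_from <- function(cfg) {
  feature_settings(window_s = cfg$features$window_s,
                   hp_cutoff_hz = cfg$features$hp_cutoff_hz,
                   hp_order = cfg$features$hp_order,
                   lp_cutoff_hz = cfg$features$lp_cutoff_hz,
                   lp_order = cfg$features$lp_order)
}
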