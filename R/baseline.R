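# Threshold-based comparator: per-parameter upper/lower falling thresholds
# derived from boxplot statistics of the fall trials' peak values, and a
# trial-level peak rule for classification.

#' Upper and lower peaks of a trial
#'
#' @param feats a `feature_series`.
#' @param param one of [feature_params()].
#' @return Named numeric vector `c(upper = max, lower = min)` of the
#'   parameter over the trial.
#' @export
trial_peaks <- function(feats, param) {
  if (!param %in% feature_params()) stop("unknown parameter: ", param)
  v <- feats[[param]]
  if (length(v) == 0) stop("empty feature series")
  c(upper = max(v), lower = min(v))
}

#' Peak table over a set of trials
#'
#' @param feature_list list of `feature_series`, one per trial.
#' @param is_fall logical vector aligned with `feature_list`.
#' @param params parameters to tabulate.
#' @return Data frame with one row per trial: `is_fall`, then
#'   `<param>_upper` and `<param>_lower` columns.
#' @export
peak_table <- function(feature_list, is_fall, params = feature_params()) {
  rows <- lapply(feature_list, function(f) {
    v <- unlist(lapply(params, function(p) trial_peaks(f, p)))
    names(v) <- as.vector(outer(c("upper", "lower"), params,
                                function(s, p) paste(p, s, sep = "_")))
    v
  })
  df <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(is_fall = is_fall), df)
}

# Boxplot whisker fences on a sample (quartiles via stats::quantile type 7).
whisker_fences <- function(x, whisker = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  if (!is.finite(whisker)) return(c(lower = -Inf, upper = Inf))
  c(lower = q[1] - whisker * iqr, upper = q[2] + whisker * iqr)
}

#' Fit boxplot-derived falling thresholds
#'
#' For each parameter, the upper falling threshold is the lower boxplot
#' whisker of the fall trials' upper peaks (the smallest peak not flagged as
#' a low outlier), and the lower falling threshold is the upper whisker of
#' the fall trials' lower peaks. With `whisker = Inf` the thresholds reduce
#' to the plain min / max of the fall peaks.
#'
#' @param peaks a [peak_table()] (only rows with `is_fall` are used).
#' @param params parameters to fit.
#' @param whisker IQR multiplier of the boxplot whiskers.
#' @return A `fall_thresholds` object: data frame with one row per
#'   parameter (`param`, `upper_fall_threshold`, `lower_fall_threshold`)
#'   plus the fall peak table as attribute `peaks`.
#' @export
fit_thresholds <- function(peaks, params = feature_params(), whisker = 1.5) {
  fall <- peaks[peaks$is_fall, , drop = FALSE]
  if (nrow(fall) == 0) stop("no fall trials in the peak table")
  rows <- lapply(params, function(p) {
    up <- fall[[paste0(p, "_upper")]]
    lo <- fall[[paste0(p, "_lower")]]
    fence_up <- whisker_fences(up, whisker)["lower"]
    fence_lo <- whisker_fences(lo, whisker)["upper"]
    data.frame(param = p,
               upper_fall_threshold = min(up[up >= fence_up]),
               lower_fall_threshold = max(lo[lo <= fence_lo]))
  })
  out <- do.call(rbind, rows)
  attr(out, "peaks") <- fall
  attr(out, "whisker") <- whisker
  class(out) <- c("fall_thresholds", "data.frame")
  out
}

#' Threshold-rule classification of trials
#'
#' A trial is called a fall when its upper peak reaches the parameter's
#' upper falling threshold or its lower peak reaches the lower falling
#' threshold — for the chosen parameter (`single_param`) or for any of the
#' fitted parameters (`any_param`, the logical OR over parameters).
#'
#' @param peaks a [peak_table()] of the trials to classify.
#' @param model a `fall_thresholds` object.
#' @param rule `"any_param"` or `"single_param"`.
#' @param param the parameter when `rule = "single_param"`.
#' @param side `"both"`, `"upper"` or `"lower"`: which threshold(s) may
#'   trigger the call.
#' @return Logical vector: `TRUE` = classified as fall.
#' @export
classify_threshold <- function(peaks, model,
                               rule = c("any_param", "single_param"),
                               param = NULL, side = c("both", "upper",
                                                      "lower")) {
  rule <- match.arg(rule)
  side <- match.arg(side)
  use <- if (rule == "single_param") {
    if (is.null(param) || !param %in% model$param)
      stop("single_param rule needs a fitted parameter")
    param
  } else model$param
  hit <- rep(FALSE, nrow(peaks))
  for (p in use) {
    thr <- model[model$param == p, ]
    up_hit <- peaks[[paste0(p, "_upper")]] >= thr$upper_fall_threshold
    lo_hit <- peaks[[paste0(p, "_lower")]] <= thr$lower_fall_threshold
    hit <- hit | switch(side, both = up_hit | lo_hit, upper = up_hit,
                        lower = lo_hit)
  }
  hit
}

#' Write / read a threshold model as text
#' @param model a `fall_thresholds` object.
#' @param path file path.
#' @export
write_thresholds <- function(model, path) {
  utils::write.csv(as.data.frame(model), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("fall_thresholds", "data.frame")
  df
}
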