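# Metrics: sensitivity / specificity / accuracy from counts, frame-label to
# alarm-event aggregation, greedy event matching against ground truth, and
# false positives per hour for continuous monitoring.

#' Aggregate frame labels into alarm events
#'
#' Maximal runs of +1 frames lasting at least `min_on_s` become detected
#' events; events separated by a gap shorter than `merge_gap_s` are merged,
#' so one fall's impact and aftermath raise a single alarm.
#'
#' @param labels integer vector of +1 / -1 frame decisions.
#' @param fs sampling rate in Hz.
#' @param min_on_s minimum run duration, seconds (default 0.05, half the
#'   fast-changed-vector window: long enough to reject isolated noise
#'   flickers, short enough to keep the alarm of a brief genuine impact).
#' @param merge_gap_s merge gap, seconds.
#' @return Data frame `start_s, end_s` (possibly zero rows), time-ordered
#'   and non-overlapping.
#' @export
frames_to_events <- function(labels, fs, min_on_s = 0.05, merge_gap_s = 2.0) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(labels) == 0) return(empty)
  r <- rle(as.integer(labels) > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  if (length(on) == 0) return(empty)
  ev <- data.frame(start_s = (starts[on] - 1) / fs, end_s = ends[on] / fs)
  # duration floor on raw runs first, then gap merging
  ev <- ev[ev$end_s - ev$start_s >= min_on_s - 1e-9, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)
  merged <- ev[1, ]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      last <- nrow(merged)
      if (ev$start_s[i] - merged$end_s[last] < merge_gap_s)
        merged$end_s[last] <- ev$end_s[i]
      else merged <- rbind(merged, ev[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Build an event log
#'
#' @param detected data frame `start_s, end_s` of detected events.
#' @param truth data frame `start_s, end_s` (optionally `adl_id`) of
#'   ground-truth fall events.
#' @param tol_s match tolerance in seconds.
#' @return An `event_log` object.
#' @export
event_log <- function(detected, truth, tol_s = 2.0) {
  chk <- function(df) {
    if (nrow(df) > 1) {
      df <- df[order(df$start_s), , drop = FALSE]
      if (any(df$start_s[-1] < df$end_s[-nrow(df)]))
        stop("events within a log must be non-overlapping")
    }
    df
  }
  structure(list(detected = chk(detected), truth = chk(truth),
                 tol_s = tol_s), class = "event_log")
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching in time order: a detected event matches a
#' truth event when their intervals, dilated by `tol_s`, overlap. Unmatched
#' truth events are false negatives, unmatched detections false positives.
#'
#' @param log an [event_log()] (or a list with `detected` and `truth`).
#' @param tol_s tolerance override, seconds.
#' @return Named integer vector `c(tp, fn, fp)`.
#' @export
match_events <- function(log, tol_s = NULL) {
  tol <- tol_s %||% log$tol_s %||% 2.0
  det <- log$detected
  tru <- log$truth
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  if (nrow(tru) > 0) for (i in seq_len(nrow(tru))) {
    cand <- which(!used & det$start_s <= tru$end_s[i] + tol &
                    det$end_s >= tru$start_s[i] - tol)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fn = nrow(tru) - tp, fp = sum(!used))
}

#' Summarize classification counts into an evaluation report
#'
#' Percentages follow the standard definitions: sensitivity
#' `100 * tp / (tp + fn)`, specificity `100 * tn / (tn + fp)`, accuracy
#' `100 * (tp + tn) / total`. A metric with a zero denominator is reported
#' as `NA` (undefined), never as 0 or 100.
#'
#' @param tp,tn,fp,fn counts.
#' @param per_adl optional data frame with columns `adl_id`, `n_false`, and
#'   per-class totals `n_total`; an error-rate column is added.
#' @return An `eval_report` list with the counts and percentage metrics.
#' @export
summarize_counts <- function(tp, tn = 0, fp = 0, fn = 0, per_adl = NULL) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rep <- list(tp = tp, tn = tn, fp = fp, fn = fn,
              sensitivity = pct(tp, tp + fn),
              specificity = pct(tn, tn + fp),
              accuracy = pct(tp + tn, tp + tn + fp + fn))
  if (!is.null(per_adl)) {
    per_adl$false_rate <- ifelse(per_adl$n_total > 0,
                                 100 * per_adl$n_false / per_adl$n_total,
                                 NA_real_)
    rep$per_adl <- per_adl
  }
  class(rep) <- "eval_report"
  rep
}

#' Summarize per-trial (or per-frame) decisions
#'
#' @param predicted logical or +1/-1 decisions.
#' @param actual logical or +1/-1 ground truth, positive = fall.
#' @param adl_id optional per-case ADL ids for the per-class error table.
#' @return An `eval_report`.
#' @export
summarize_decisions <- function(predicted, actual, adl_id = NULL) {
  p <- as.integer(predicted) > 0
  a <- as.integer(actual) > 0
  if (length(p) != length(a)) stop("length mismatch")
  if (length(p) == 0) stop("no decisions to summarize")
  per_adl <- NULL
  if (!is.null(adl_id)) {
    err <- p != a
    per_adl <- do.call(rbind, lapply(sort(unique(adl_id)), function(id) {
      sel <- adl_id == id
      data.frame(adl_id = id, n_false = sum(err[sel]), n_total = sum(sel))
    }))
  }
  summarize_counts(tp = sum(p & a), tn = sum(!p & !a), fp = sum(p & !a),
                   fn = sum(!p & a), per_adl = per_adl)
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("<eval_report> TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn,
              x$fp, x$fn))
  cat(sprintf("  sensitivity %s  specificity %s  accuracy %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy)))
  if (!is.null(x$fp_per_hour))
    cat(sprintf("  false positives per hour: %.3f\n", x$fp_per_hour))
  if (!is.null(x$per_adl)) {
    cat("  per-ADL errors:\n")
    print(x$per_adl, row.names = FALSE)
  }
  invisible(x)
}

#' False-positive rate per hour
#'
#' @param fp number of false-positive events.
#' @param duration_min monitored duration in minutes (> 0).
#' @return Events per hour.
#' @export
fp_rate <- function(fp, duration_min) {
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("duration must be positive")
  fp / (duration_min / 60)
}
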