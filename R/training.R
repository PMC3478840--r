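# Building the labeled frame set: the per-trial 0.87-of-peak rule marks the
# falling range on the fast-changed-vector profile, every sample of every
# selected trial becomes a training frame, and trial selection / two-fold
# splits are seeded.

#' Fall-frame threshold for one falling trial
#'
#' The falling range of a fall recording is marked on its fast-changed-vector
#' profile: the trial's maximum `CV_Fast`, multiplied by a factor (default
#' 0.87), is the frame-labeling threshold for that trial.
#'
#' @param cv_fast the trial's fast-changed-vector series (g).
#' @param factor multiplier on the trial maximum.
#' @return Threshold in g.
#' @export
fall_frame_threshold <- function(cv_fast, factor = 0.87) {
  if (length(cv_fast) == 0 || max(cv_fast) <= 0)
    stop("no fall signature: cv_fast has no positive excursion")
  factor * max(cv_fast)
}

#' Label the frames of one trial
#'
#' Fall trials get +1 on samples whose `CV_Fast` exceeds the trial threshold
#' and -1 elsewhere; non-fall trials are -1 throughout. Since the threshold is
#' a fraction below the trial maximum, every fall trial contributes at least
#' one positive frame.
#'
#' @param feats a `feature_series` for the trial.
#' @param is_fall logical, whether the trial is a falling ADL.
#' @param threshold threshold in g from [fall_frame_threshold()]; required
#'   when `is_fall`.
#' @return Integer vector of +1 / -1, one per sample.
#' @export
label_trial <- function(feats, is_fall, threshold = NULL) {
  n <- nrow(feats)
  if (!is_fall) return(rep(-1L, n))
  if (is.null(threshold)) stop("a fall trial needs a labeling threshold")
  ifelse(feats$cv_fast > threshold, 1L, -1L)
}

#' Assemble a labeled training frame set
#'
#' Randomly selects `select` trials per (subject, ADL) cell, extracts (or
#' reuses) features, labels every frame with the per-trial rule, and stacks
#' the requested parameter combination into a frame matrix. Selection is
#' deterministic given `seed` and invariant to manifest row order.
#'
#' @param manifest a [trial_manifest()].
#' @param select trials per (subject, ADL) cell; every cell must have at
#'   least this many.
#' @param params character vector, a subset of [feature_params()].
#' @param seed integer seed for the trial selection.
#' @param factor fall-frame threshold factor.
#' @param cfg feature settings, used when features must be computed.
#' @param features optional named list of precomputed `feature_series`, keyed
#'   by manifest `path`; entries found here skip file I/O.
#' @param fs sampling rate used when reading trace files.
#' @param negative_stride,positive_stride keep every k-th negative / positive
#'   frame (default 1: all frames enter the matrix). A stride > 1 caps the
#'   quadratic cost of kernel SVM training on long recordings; the positive
#'   frame of each fall trial's peak is always kept.
#' @param keep_negatives_above hard-negative mining for thinned sets: when
#'   `negative_stride > 1`, negative frames of non-fall trials whose
#'   `cv_fast` exceeds this level (g) are kept regardless of the stride, so
#'   the impact-like bumps of energetic non-fall activities stay
#'   represented. Default 1.0 g.
#' @return A `labeled_frames` object: list with the `m x n` matrix `X`,
#'   labels `D` (+1/-1), `provenance` data frame (subject, adl_id, trial,
#'   sample), `params`, and selected-trial counts (`n_fall_trials`,
#'   `n_nonfall_trials`).
#' @export
assemble_training_set <- function(manifest, select = 5,
                                  params = feature_params(), seed = 1,
                                  factor = 0.87, cfg = feature_settings(),
                                  features = NULL, fs = 200,
                                  negative_stride = 1L, positive_stride = 1L,
                                  keep_negatives_above = 1.0) {
  if (select < 1) stop("select must be >= 1 (empty training set requested)")
  stopifnot(all(params %in% feature_params()), length(params) >= 1)
  mf <- as.data.frame(manifest)
  mf <- mf[order(mf$subject, mf$adl_id, mf$trial), , drop = FALSE]
  cells <- split(mf, list(mf$subject, mf$adl_id), drop = TRUE)
  chosen <- list()
  with_seed(seed, {
    # deterministic cell order, independent of manifest row order
    ord <- order(vapply(cells, function(cl) cl$subject[1], integer(1)),
                 vapply(cells, function(cl) cl$adl_id[1], integer(1)))
    for (cl in cells[ord]) {
      if (nrow(cl) < select)
        stop(sprintf("subject %d, ADL %d has %d trials; %d required",
                     cl$subject[1], cl$adl_id[1], nrow(cl), select))
      idx <- sort(sample.int(nrow(cl), select))
      chosen[[length(chosen) + 1]] <- cl[idx, , drop = FALSE]
    }
  })
  sel <- do.call(rbind, chosen)
  get_feats <- function(row) {
    f <- if (!is.null(features)) features[[row$path]] else NULL
    if (is.null(f)) f <- extract_features(read_trace(row$path, fs = fs), cfg)
    f
  }
  Xs <- vector("list", nrow(sel))
  Ds <- vector("list", nrow(sel))
  prov <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    row <- sel[i, ]
    f <- get_feats(row)
    lab <- if (row$is_fall)
      label_trial(f, TRUE, fall_frame_threshold(f$cv_fast, factor))
    else label_trial(f, FALSE)
    keep <- subsample_frames(lab, f$cv_fast, negative_stride, positive_stride,
                             if (row$is_fall) Inf else keep_negatives_above)
    Xs[[i]] <- as.matrix(as.data.frame(f)[keep, params, drop = FALSE])
    Ds[[i]] <- lab[keep]
    prov[[i]] <- data.frame(subject = row$subject, adl_id = row$adl_id,
                            trial = row$trial, sample = keep)
  }
  out <- list(X = do.call(rbind, Xs), D = as.integer(unlist(Ds)),
              provenance = do.call(rbind, prov), params = params,
              n_fall_trials = sum(sel$is_fall),
              n_nonfall_trials = sum(!sel$is_fall))
  rownames(out$X) <- NULL
  class(out) <- "labeled_frames"
  out
}

# Deterministic frame thinning; keeps the peak positive frame of the trial
# and (when thinning) all impact-like negative frames.
subsample_frames <- function(lab, cvf, negative_stride, positive_stride,
                             keep_negatives_above = Inf) {
  pos <- which(lab > 0)
  neg <- which(lab < 0)
  ps <- max(1L, as.integer(positive_stride))
  ns <- max(1L, as.integer(negative_stride))
  keep_pos <- if (length(pos))
    pos[(seq_along(pos) - 1L) %% ps == 0L | pos == pos[which.max(cvf[pos])]]
  else integer(0)
  keep_neg <- neg[(seq_along(neg) - 1L) %% ns == 0L |
                    (ns > 1L & cvf[neg] > keep_negatives_above)]
  sort(unique(c(keep_pos, keep_neg)))
}

#' @export
print.labeled_frames <- function(x, ...) {
  cat(sprintf(paste0("<labeled_frames> %d frames x %d params (%s); ",
                     "%d positive, %d negative\n",
                     "  from %d fall + %d non-fall trials\n"),
              nrow(x$X), ncol(x$X), paste(x$params, collapse = ","),
              sum(x$D > 0), sum(x$D < 0),
              x$n_fall_trials, x$n_nonfall_trials))
  invisible(x)
}

#' Write / read a labeled frame set as delimited text
#' @param frames a `labeled_frames` object.
#' @param path file path.
#' @export
write_frames <- function(frames, path) {
  df <- cbind(as.data.frame(frames$X), label = frames$D, frames$provenance)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# params: %s", paste(frames$params, collapse = ",")), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  hdr <- readLines(path, n = 1)
  params <- strsplit(sub("^#\\s*params:\\s*", "", hdr), ",")[[1]]
  df <- utils::read.csv(path, comment.char = "#")
  prov_cols <- c("subject", "adl_id", "trial", "sample")
  out <- list(X = as.matrix(df[params]), D = as.integer(df$label),
              provenance = df[prov_cols], params = params,
              n_fall_trials = NA_integer_, n_nonfall_trials = NA_integer_)
  class(out) <- "labeled_frames"
  out
}

#' Two-fold cross-validation split of a manifest
#'
#' `by_trial` halves the trials within every (subject, ADL) cell, training
#' and testing on the same individuals; `by_subject` assigns whole subjects
#' to disjoint halves. Both are seeded and row-order invariant.
#'
#' @param manifest a [trial_manifest()].
#' @param mode `"by_trial"` or `"by_subject"`.
#' @param seed integer seed.
#' @return List with `train` and `test` manifests (disjoint; union is the
#'   input).
#' @export
split_cv <- function(manifest, mode = c("by_trial", "by_subject"), seed = 1) {
  mode <- match.arg(mode)
  mf <- as.data.frame(manifest)
  mf <- mf[order(mf$subject, mf$adl_id, mf$trial), , drop = FALSE]
  take <- logical(nrow(mf))
  with_seed(seed, {
    if (mode == "by_trial") {
      cells <- split(seq_len(nrow(mf)), list(mf$subject, mf$adl_id),
                     drop = TRUE)
      ord <- order(vapply(cells, function(ix) mf$subject[ix[1]], integer(1)),
                   vapply(cells, function(ix) mf$adl_id[ix[1]], integer(1)))
      for (ix in cells[ord]) {
        if (length(ix) < 2)
          stop("by_trial split needs >= 2 trials per (subject, ADL) cell")
        k <- floor(length(ix) / 2)
        take[ix[sample.int(length(ix), k)]] <- TRUE
      }
    } else {
      subj <- sort(unique(mf$subject))
      if (length(subj) < 2) stop("by_subject split needs >= 2 subjects")
      k <- floor(length(subj) / 2)
      half <- subj[sample.int(length(subj), k)]
      take[mf$subject %in% half] <- TRUE
    }
  })
  remake <- function(df) trial_manifest(df$path, df$subject, df$adl_id,
                                        df$trial)
  list(train = remake(mf[take, , drop = FALSE]),
       test = remake(mf[!take, , drop = FALSE]))
}
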