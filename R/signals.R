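#' Construct a tri-axial acceleration trace
#'
#' An `accel_trace` is the raw input of the whole pipeline: a uniformly
#' sampled tri-axial accelerometer series in g units from a waist-mounted
#' sensor, plus sampling-rate metadata. With the wearer standing, the +z axis
#' points up, so gravity reads approximately (0, 0, +1) g at rest.
#'
#' @param ax,ay,az numeric vectors of equal length, acceleration in g.
#' @param fs sampling rate in Hz (default 200, the target device rate).
#' @param t optional explicit time grid in seconds; must be uniform with step
#'   `1/fs`. Synthesized from `fs` (starting at 0) when omitted.
#' @param meta named list of free-form provenance (subject id, ADL id, trial).
#' @return An object of class `accel_trace`: a data frame with columns
#'   `t, ax, ay, az` and attributes `fs` and `meta`.
#' @export
accel_trace <- function(ax, ay, az, fs = 200, t = NULL, meta = list()) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    stop("ax, ay, az must have equal length")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(t)) {
    t <- if (n > 0) (seq_len(n) - 1) / fs else numeric(0)
  } else {
    if (length(t) != n) stop("t must match the sample count")
    if (n > 1) {
      steps <- diff(t)
      if (any(steps <= 0) || max(abs(steps - 1 / fs)) > 1e-9)
        stop("t must be strictly increasing with constant step 1/fs")
    }
  }
  out <- data.frame(t = as.numeric(t), ax = as.numeric(ax),
                    ay = as.numeric(ay), az = as.numeric(az))
  structure(out, fs = as.numeric(fs), meta = meta,
            class = c("accel_trace", "data.frame"))
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.2f s)\n",
              nrow(x), attr(x, "fs"),
              if (nrow(x) > 0) nrow(x) / attr(x, "fs") else 0))
  meta <- attr(x, "meta")
  if (length(meta))
    cat("  meta:", paste(names(meta), unlist(meta), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Sampling rate of a trace
#' @param trace an `accel_trace`.
#' @return Sampling rate in Hz.
#' @export
trace_fs <- function(trace) attr(trace, "fs")

is_accel_trace <- function(x) inherits(x, "accel_trace")

assert_trace <- function(trace) {
  if (!is_accel_trace(trace)) stop("expected an accel_trace")
  invisible(trace)
}

#' Read an acceleration trace from delimited text
#'
#' Accepts comma- or whitespace-delimited files with 3 numeric columns
#' (ax, ay, az; a time grid is synthesized from `fs`) or 4 columns
#' (t, ax, ay, az; timestamps must be uniform). Lines starting with `#` are
#' treated as comments; `# key: value` comments are parsed back into `meta`.
#' A single non-numeric header line is skipped.
#'
#' @param path file path.
#' @param fs sampling rate in Hz, used to synthesize or check the grid.
#' @return An [accel_trace()].
#' @export
read_trace <- function(path, fs = 200) {
  lines <- readLines(path)
  meta <- list()
  iscomment <- startsWith(trimws(lines), "#")
  for (cl in lines[iscomment]) {
    m <- regmatches(cl, regexec("^#\\s*([^:]+):\\s*(.*)$", cl))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!iscomment & nzchar(trimws(lines))]
  rowno <- which(!iscomment & nzchar(trimws(lines)))
  if (length(body) == 0) return(accel_trace(numeric(0), numeric(0), numeric(0),
                                            fs = fs, meta = meta))
  split_row <- function(s) {
    s <- trimws(s)
    if (grepl(",", s, fixed = TRUE)) strsplit(s, "\\s*,\\s*")[[1]]
    else strsplit(s, "\\s+")[[1]]
  }
  cells <- lapply(body, split_row)
  # optional single header line of non-numeric tokens
  first_num <- suppressWarnings(as.numeric(cells[[1]]))
  if (anyNA(first_num)) {
    cells <- cells[-1]
    rowno <- rowno[-1]
    if (length(cells) == 0)
      return(accel_trace(numeric(0), numeric(0), numeric(0), fs = fs,
                         meta = meta))
  }
  ncols <- lengths(cells)
  if (any(ncols != ncols[1]))
    stop(sprintf("inconsistent column count at line %d of %s",
                 rowno[which(ncols != ncols[1])[1]], path))
  if (!ncols[1] %in% c(3, 4))
    stop("trace files must have 3 (ax,ay,az) or 4 (t,ax,ay,az) columns")
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(ncols[1])))
  bad <- which(apply(is.na(vals), 2, any))
  if (length(bad))
    stop(sprintf("non-numeric value at line %d of %s", rowno[bad[1]], path))
  vals <- t(vals)
  if (ncols[1] == 3) {
    accel_trace(vals[, 1], vals[, 2], vals[, 3], fs = fs, meta = meta)
  } else {
    tt <- vals[, 1]
    if (nrow(vals) > 1) {
      steps <- diff(tt)
      offby <- abs(steps - 1 / fs)
      if (any(steps <= 0) || max(offby) > 1e-9)
        stop(sprintf("non-uniform timestamps near line %d of %s",
                     rowno[which.max(offby) + 1], path))
    }
    accel_trace(vals[, 2], vals[, 3], vals[, 4], fs = fs, t = tt, meta = meta)
  }
}

#' Write an acceleration trace to delimited text
#'
#' Deterministic 4-column CSV with header `t,ax,ay,az`, 6 decimal places,
#' metadata serialized as leading `# key: value` comment lines.
#'
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(trace, "meta")
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  writeLines(sprintf("# fs: %g", trace_fs(trace)), con)
  writeLines("t,ax,ay,az", con)
  if (nrow(trace) > 0)
    writeLines(sprintf("%.6f,%.6f,%.6f,%.6f",
                       trace$t, trace$ax, trace$ay, trace$az), con)
  invisible(path)
}

adl_catalog_df <- function() {
  data.frame(
    adl_id = 1:21,
    name = c("Slip and ascending stairs", "Slip and descending stairs",
             "Forward fall", "Backward fall", "Falling down from bed",
             "Fall down from wheelchair", "Rolling down from bed",
             "Lateral fall", "Falling down to bed", "Fall for the weak leg",
             "Ascending stairs", "Descending stairs", "Sitting down on bed",
             "Standing up from bed", "Sitting down in wheelchair",
             "Standing up from wheelchair", "Walking", "Lying down",
             "Lying up", "Squatting down", "Standing up"),
    is_fall = rep(c(TRUE, FALSE), c(10, 11)),
    stringsAsFactors = FALSE)
}

#' The 21-class ADL catalog
#'
#' Classes 1-10 are falling ADLs (the body's center of gravity descends
#' quickly, including soft falls involving beds and wheelchairs); classes
#' 11-21 are non-falling ADLs.
#'
#' @return Data frame with columns `adl_id`, `name`, `is_fall`.
#' @export
adl_catalog <- function() adl_catalog_df()

#' Build a trial manifest
#'
#' A manifest maps recording files to (subject, ADL class, trial index). The
#' `is_fall` flag is derived from the ADL id (1-10 falling, 11-21 not) and
#' checked if supplied.
#'
#' @param path character vector of file paths (may be empty strings for
#'   in-memory workflows).
#' @param subject,adl_id,trial integer vectors, recycled to a common length.
#' @param is_fall optional logical; must agree with the catalog if given.
#' @return Data frame of class `trial_manifest`.
#' @export
trial_manifest <- function(path, subject, adl_id, trial, is_fall = NULL) {
  n <- max(length(path), length(subject), length(adl_id), length(trial))
  df <- data.frame(path = rep_len(as.character(path), n),
                   subject = rep_len(as.integer(subject), n),
                   adl_id = rep_len(as.integer(adl_id), n),
                   trial = rep_len(as.integer(trial), n),
                   stringsAsFactors = FALSE)
  if (any(df$adl_id < 1 | df$adl_id > 21)) stop("adl_id must be in 1..21")
  derived <- df$adl_id <= 10
  if (!is.null(is_fall) && !all(as.logical(is_fall) == derived))
    stop("is_fall flags disagree with ADL ids (1-10 are falls)")
  df$is_fall <- derived
  key <- paste(df$subject, df$adl_id, df$trial)
  if (anyDuplicated(key))
    stop("duplicate (subject, adl_id, trial) entries in manifest")
  structure(df, class = c("trial_manifest", "data.frame"))
}

#' Read / write a trial manifest
#'
#' Delimited text with header `path,subject,adl_id,trial,is_fall`.
#'
#' @param path file path.
#' @return [trial_manifest()] for `read_manifest`; `path` invisibly for
#'   `write_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("path", "subject", "adl_id", "trial")
  if (!all(need %in% names(df)))
    stop("manifest must have columns path,subject,adl_id,trial")
  trial_manifest(df$path, df$subject, df$adl_id, df$trial,
                 is_fall = if ("is_fall" %in% names(df)) df$is_fall else NULL)
}

#' @rdname read_manifest
#' @param manifest a [trial_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
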