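#' Total sum vector
#'
#' Per-sample Euclidean magnitude of the three acceleration axes,
#' `SV_Total(t) = sqrt(Ax^2 + Ay^2 + Az^2)`. Contains both the static
#' (gravity) and dynamic components; approximately 1 g at rest.
#'
#' @param trace an [accel_trace()].
#' @return Numeric vector in g, one value per sample.
#' @export
sv_total <- function(trace) {
  assert_trace(trace)
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}

#' Fast changed vector
#'
#' Root-sum-square over the three axes of the (max - min) acceleration within
#' a sliding window (default 0.1 s). The window is causal: it ends at the
#' current sample, and the first samples use a partial window. This is the
#' impact-sensitive feature; a fall's impact spike produces a large excursion
#' within the window on at least one axis.
#'
#' @param trace an [accel_trace()].
#' @param window_s window length in seconds; `window_s * fs` must be >= 2
#'   samples.
#' @return Numeric vector in g, one value per sample.
#' @export
cv_fast <- function(trace, window_s = 0.1) {
  assert_trace(trace)
  fs <- trace_fs(trace)
  w <- as.integer(ceiling(window_s * fs - 1e-9))
  if (w < 2) stop("window must span at least 2 samples")
  if (nrow(trace) == 0) return(numeric(0))
  dx <- cpp_sliding_range(trace$ax, w)
  dy <- cpp_sliding_range(trace$ay, w)
  dz <- cpp_sliding_range(trace$az, w)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Dynamic sum vector
#'
#' The total-sum-vector formula applied to high-pass filtered axes: the
#' magnitude of body motion with the gravity DC removed. The filter is a
#' causal per-axis Butterworth high-pass (default order 4, cutoff 0.3 Hz),
#' which passes body dynamics (> 0.5 Hz) while rejecting the static
#' component.
#'
#' @param trace an [accel_trace()].
#' @param hp_cutoff_hz high-pass cutoff in Hz; must be below `fs/2`.
#' @param hp_order filter order.
#' @return Numeric vector in g.
#' @export
sv_d <- function(trace, hp_cutoff_hz = 0.3, hp_order = 4) {
  assert_trace(trace)
  fs <- trace_fs(trace)
  cf <- butter_coeffs(hp_order, hp_cutoff_hz, fs, "high")
  if (nrow(trace) == 0) return(numeric(0))
  fx <- iir_filter(cf, trace$ax)
  fy <- iir_filter(cf, trace$ay)
  fz <- iir_filter(cf, trace$az)
  sqrt(fx^2 + fy^2 + fz^2)
}

#' Vertical acceleration
#'
#' Law-of-cosines projection of the dynamic acceleration onto the gravity
#' axis: `VA = (SV_Total^2 - SV_D^2 - |G|^2) / (2 |G|)`, signed. Zero at
#' rest, negative during free fall (-0.5 g in the ideal free-fall limit where
#' both magnitudes vanish), and exactly the injected amplitude for purely
#' vertical dynamics.
#'
#' @param sv_total,sv_d aligned numeric series in g.
#' @param g_mag gravity magnitude in g units (1 by definition here).
#' @return Numeric vector in g.
#' @export
vertical_acceleration <- function(sv_total, sv_d, g_mag = 1.0) {
  if (length(sv_total) != length(sv_d)) stop("series length mismatch")
  (sv_total^2 - sv_d^2 - g_mag^2) / (2 * g_mag)
}

#' Posture angle
#'
#' Angle in degrees between the low-pass estimate of the gravity vector and
#' the upright reference direction (0, 0, +1). A standing wearer reads about
#' 0 degrees, lying about 90, inverted 180. The low-pass (default Butterworth
#' order 2, cutoff 0.3 Hz) isolates the quasi-static orientation from body
#' dynamics; being causal, it needs a few seconds to settle from its zero
#' initial state.
#'
#' Samples where the filtered vector has near-zero magnitude (mostly the
#' filter startup) carry the previous sample's angle forward and are flagged
#' in the `degenerate` attribute.
#'
#' @param trace an [accel_trace()].
#' @param lp_cutoff_hz low-pass cutoff in Hz.
#' @param lp_order filter order.
#' @param upright length-3 unit reference direction of gravity when standing.
#' @return Numeric vector of angles in `[0, 180]` degrees with a logical
#'   `degenerate` attribute marking carried-forward samples.
#' @export
posture_angle <- function(trace, lp_cutoff_hz = 0.3, lp_order = 2,
                          upright = c(0, 0, 1)) {
  assert_trace(trace)
  fs <- trace_fs(trace)
  if (nrow(trace) == 0) return(numeric(0))
  cf <- butter_coeffs(lp_order, lp_cutoff_hz, fs, "low")
  gx <- iir_filter(cf, trace$ax)
  gy <- iir_filter(cf, trace$ay)
  gz <- iir_filter(cf, trace$az)
  u <- upright / sqrt(sum(upright^2))
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  dot <- gx * u[1] + gy * u[2] + gz * u[3]
  ang <- rep(NA_real_, length(mag))
  ok <- mag > 1e-6
  ang[ok] <- acos(pmin(1, pmax(-1, dot[ok] / mag[ok]))) * 180 / pi
  # carry-forward for degenerate samples; default upright before any valid one
  if (any(!ok)) {
    last <- 0
    for (i in seq_along(ang)) {
      if (is.na(ang[i])) ang[i] <- last else last <- ang[i]
    }
  }
  attr(ang, "degenerate") <- !ok
  ang
}

#' Default feature-extraction settings
#'
#' @param window_s sliding window for the fast changed vector, seconds.
#' @param hp_cutoff_hz,hp_order high-pass design for the dynamic sum vector.
#' @param lp_cutoff_hz,lp_order low-pass design for the posture angle.
#' @param g_mag gravity magnitude in g.
#' @param upright upright gravity direction in the sensor frame.
#' @return Named list of settings.
#' @export
feature_settings <- function(window_s = 0.1, hp_cutoff_hz = 0.3, hp_order = 4,
                             lp_cutoff_hz = 0.3, lp_order = 2, g_mag = 1.0,
                             upright = c(0, 0, 1)) {
  list(window_s = window_s, hp_cutoff_hz = hp_cutoff_hz, hp_order = hp_order,
       lp_cutoff_hz = lp_cutoff_hz, lp_order = lp_order, g_mag = g_mag,
       upright = upright)
}

#' Extract the four action parameters of a trace
#'
#' Bundles the total sum vector, fast changed vector, vertical acceleration
#' and posture angle on the trace's timeline. All four series have exactly
#' the trace's length; causal edge effects are confined to the first few
#' seconds (window warm-up and filter settling).
#'
#' @param trace an [accel_trace()].
#' @param cfg settings from [feature_settings()].
#' @return A `feature_series`: data frame with columns
#'   `t, sv_total, cv_fast, va, phi_z` (g, g, g, degrees) plus an `fs`
#'   attribute.
#' @export
extract_features <- function(trace, cfg = feature_settings()) {
  assert_trace(trace)
  svt <- sv_total(trace)
  cvf <- cv_fast(trace, cfg$window_s)
  svd <- sv_d(trace, cfg$hp_cutoff_hz, cfg$hp_order)
  va <- vertical_acceleration(svt, svd, cfg$g_mag)
  phi <- posture_angle(trace, cfg$lp_cutoff_hz, cfg$lp_order, cfg$upright)
  out <- data.frame(t = trace$t, sv_total = svt, cv_fast = cvf, va = va,
                    phi_z = as.numeric(phi))
  structure(out, fs = trace_fs(trace), meta = attr(trace, "meta"),
            class = c("feature_series", "data.frame"))
}

#' Read / write a feature series
#'
#' Delimited text with header `t,sv_total,cv_fast,va,phi_z`.
#' @param path file path.
#' @param fs sampling rate in Hz (for `read_features`).
#' @export
read_features <- function(path, fs = 200) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "sv_total", "cv_fast", "va", "phi_z")
  if (!all(need %in% names(df)))
    stop("feature files need columns t,sv_total,cv_fast,va,phi_z")
  structure(df[need], fs = fs, class = c("feature_series", "data.frame"))
}

#' @rdname read_features
#' @param feats a `feature_series`.
#' @export
write_features <- function(feats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t,sv_total,cv_fast,va,phi_z", con)
  if (nrow(feats) > 0)
    writeLines(sprintf("%.6f,%.6f,%.6f,%.6f,%.6f", feats$t, feats$sv_total,
                       feats$cv_fast, feats$va, feats$phi_z), con)
  invisible(path)
}

#' Names of the four action parameters
#' @return `c("sv_total", "cv_fast", "va", "phi_z")`.
#' @export
feature_params <- function() c("sv_total", "cv_fast", "va", "phi_z")
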