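# Butterworth IIR design via the bilinear transform. No DSP package ships
# with the target environment, so the design lives here; it is checked
# behaviourally (DC rejection, passband gain) and against an external
# reference in the test suite.

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0 + 0i) - c(0 + 0i, p * rt)
  p
}

polyval_c <- function(p, z) {
  acc <- complex(real = 0)
  for (c in p) acc <- acc * z + c
  acc
}

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth low- or high-pass filter (bilinear transform
#' of the analog prototype) and returns transfer-function coefficients
#' normalized so `a[1] == 1`.
#'
#' @param order filter order (>= 1).
#' @param cutoff_hz -3 dB cutoff in Hz; must satisfy `0 < cutoff < fs/2`.
#' @param fs sampling rate in Hz.
#' @param type `"high"` or `"low"`.
#' @return List with numerator `b` and denominator `a`.
#' @export
butter_coeffs <- function(order, cutoff_hz, fs, type = c("high", "low")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2))
    stop("cutoff must satisfy 0 < cutoff < fs/2")
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)  # prewarped analog cutoff, rad/s
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP unit poles
  if (type == "low") {
    pa <- wc * proto
    za <- complex(0)
  } else {
    pa <- wc / proto
    za <- rep(0 + 0i, order)
  }
  pz <- (2 * fs + pa) / (2 * fs - pa)
  zz <- if (length(za)) (2 * fs + za) / (2 * fs - za) else rep(-1 + 0i, order)
  b <- Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  z0 <- if (type == "low") 1 + 0i else -1 + 0i  # unit gain at DC / Nyquist
  g <- abs(polyval_c(complex(real = a), z0) / polyval_c(complex(real = b), z0))
  list(b = b * g, a = a)
}

#' Apply an IIR filter causally
#'
#' Direct-form II transposed. By default the internal state starts at the
#' steady state for a constant input equal to the first sample, so a signal
#' that begins at rest produces no startup transient (a constant trace
#' high-passes to exactly zero); this stays causal and is how a real-time
#' device would prime its filter. `init = "zero"` gives the textbook
#' zero-state start, whose step transient decays over several times
#' `1 / cutoff_hz` seconds.
#'
#' @param coeffs list with `b` and `a` as from [butter_coeffs()].
#' @param x numeric signal.
#' @param init `"steady"` (default) or `"zero"` initial state.
#' @return Filtered signal, same length as `x`.
#' @export
iir_filter <- function(coeffs, x, init = c("steady", "zero")) {
  init <- match.arg(init)
  a <- coeffs$a
  b <- coeffs$b / a[1]
  a <- a / a[1]
  cpp_iir_filter(b, a, as.numeric(x), init == "steady")
}
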