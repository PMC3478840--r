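# Shared fixtures, built in code. Expensive objects are cached per test run.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# static upright trace (optionally with noise), n samples at fs
static_trace <- function(n = 1000, fs = 200, axis = c(0, 0, 1), noise = 0) {
  jitter <- function(v) if (noise > 0) v + rnorm(n, 0, noise) else rep(v, n)
  accel_trace(jitter(axis[1]), jitter(axis[2]), jitter(axis[3]), fs = fs)
}

random_trace <- function(n = 1000, fs = 200) {
  accel_trace(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5), rnorm(n, 1, 0.5), fs = fs)
}

# small scripted protocol + features, shared across tests
small_protocol <- function() {
  fx_cached("small_protocol", {
    p <- generate_protocol(subjects = 2, trials_per_adl = 2, seed = 101)
    p$features <- lapply(p$traces, extract_features)
    p
  })
}

# a small trained model on the small protocol (select 1 trial per cell)
small_model <- function() {
  fx_cached("small_model", {
    p <- small_protocol()
    ts <- assemble_training_set(p$manifest, select = 1, seed = 5,
                                features = p$features,
                                negative_stride = 40, positive_stride = 4)
    svm_train(ts)
  })
}

# brute-force oracle for the causal sliding-window range
naive_sliding_range <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - w + 1):i]
    out[i] <- max(win) - min(win)
  }
  out
}

extdata <- function(name) {
  system.file("extdata", name, package = "fallsense", mustWork = TRUE)
}
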