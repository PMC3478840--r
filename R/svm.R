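#' Gaussian radial basis kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`.
#'
#' @param x,y numeric vectors of equal length.
#' @param gamma kernel width (the detector default is 5.3).
#' @return Scalar kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("dimension mismatch")
  exp(-gamma * sum((x - y)^2))
}

#' Train the soft-margin RBF SVM fall detector
#'
#' Solves the C-SVC dual (linear slack penalties, multipliers boxed in
#' `[0, C]`) with a sequential-minimal-optimization solver using
#' maximal-violating-pair working-set selection. Only patterns with nonzero
#' multipliers — the support vectors — are stored; they define the decision
#' function together with the bias.
#'
#' Defaults are the detector's operating point: `gamma = 5.3`, `cost = 4.7`.
#' Features enter unscaled.
#'
#' @param data a `labeled_frames` set (or any list with matrix `X`, labels
#'   `D` in +1/-1, and `params`).
#' @param gamma RBF kernel width.
#' @param cost box constraint C on the multipliers.
#' @param tol SMO stopping tolerance on the maximal KKT violation.
#' @param max_iter iteration cap; exceeding it is an error (diagnostics in
#'   the message).
#' @param scale if `TRUE`, min-max scale each feature to `[0, 1]` (ranges
#'   learned from the training set, stored in the model, applied to every
#'   query). Off by default: features enter the kernel raw. With raw
#'   features the posture angle (0-180 degrees) dominates the RBF distance
#'   at gamma = 5.3, so scaling is strongly recommended for the
#'   four-parameter combination.
#' @return An object of class `fall_svm`: support vectors, multipliers
#'   `alpha`, labels `sv_labels`, `bias`, `gamma`, `cost`, `param_names`.
#' @export
svm_train <- function(data, gamma = 5.3, cost = 4.7, tol = 1e-6,
                      max_iter = 2e6, scale = FALSE) {
  X <- as.matrix(data$X)
  D <- as.numeric(data$D)
  if (!all(D %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (length(unique(D)) < 2) stop("training data contains a single class")
  if (nrow(X) != length(D)) stop("X and D disagree in length")
  if (nrow(X) > 15000)
    stop("training set too large for the dense-kernel solver; ",
         "thin frames first (see negative_stride/positive_stride)")
  scale_center <- NULL
  scale_range <- NULL
  if (isTRUE(scale)) {
    rng <- apply(X, 2, range)
    scale_center <- rng[1, ]
    scale_range <- pmax(rng[2, ] - rng[1, ], 1e-12)
    X <- sweep(sweep(X, 2, scale_center), 2, scale_range, "/")
  }
  fit <- cpp_svm_smo(X, D, cost, gamma, tol, as.integer(max_iter))
  if (!fit$converged)
    stop(sprintf("SMO did not converge within %d iterations (tol %g)",
                 as.integer(max_iter), tol))
  keep <- fit$alpha > 1e-12
  model <- list(support_vectors = X[keep, , drop = FALSE],
                alphas = fit$alpha[keep], sv_labels = D[keep],
                bias = fit$bias, gamma = gamma, cost = cost,
                param_names = data$params %||% colnames(X) %||%
                  paste0("x", seq_len(ncol(X))),
                scale_center = scale_center, scale_range = scale_range,
                iterations = fit$iterations)
  class(model) <- "fall_svm"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fall_svm <- function(x, ...) {
  cat(sprintf(paste0("<fall_svm> %d support vectors, gamma=%g, C=%g, ",
                     "bias=%.6g\n  params: %s\n"),
              length(x$alphas), x$gamma, x$cost, x$bias,
              paste(x$param_names, collapse = ",")))
  invisible(x)
}

#' Decision function of a trained model
#'
#' `score(x) = sum_j D_j alpha_j K(X_j, x) + b`; the predicted label is
#' `sign(score)` with ties (score exactly 0) resolved to -1, the
#' conservative non-fall side.
#'
#' @param model a `fall_svm`.
#' @param x numeric vector matching the model dimension, or a matrix with
#'   one pattern per row.
#' @return For a single vector, a list with `score` and `label`; for a
#'   matrix, a data frame of scores and labels.
#' @export
svm_decision <- function(model, x) {
  single <- !is.matrix(x)
  if (single) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$support_vectors)) stop("dimension mismatch")
  if (!is.null(model$scale_center))
    x <- sweep(sweep(x, 2, model$scale_center), 2, model$scale_range, "/")
  sc <- cpp_rbf_scores(model$support_vectors,
                       model$sv_labels * model$alphas, model$bias,
                       model$gamma, x)
  if (single) list(score = sc[1], label = if (sc[1] > 0) 1L else -1L)
  else data.frame(score = sc, label = ifelse(sc > 0, 1L, -1L))
}

#' Classify every frame of a feature series
#'
#' Vectorized sample-wise application of [svm_decision()] on the model's
#' parameter combination.
#'
#' @param model a `fall_svm`.
#' @param feats a `feature_series`.
#' @param params parameter combination; must equal the model's
#'   `param_names`. Defaults to the model's.
#' @return Integer vector of +1 / -1, one per sample.
#' @export
classify_series <- function(model, feats, params = model$param_names) {
  if (!identical(params, model$param_names))
    stop("parameter combination does not match the trained model")
  if (!all(params %in% names(feats)))
    stop("feature series lacks required parameters")
  if (nrow(feats) == 0) return(integer(0))
  X <- as.matrix(as.data.frame(feats)[params])
  svm_decision(model, X)$label
}

#' Save / load a trained SVM model as text
#'
#' Versioned plain-text format: header lines `key: value`
#' (format version, params, gamma, cost, bias, count), then one line per
#' support vector (`label alpha feature...`, full double precision).
#'
#' @param model a `fall_svm`.
#' @param path file path.
#' @return `path` invisibly (`save_model`); a `fall_svm` (`load_model`).
#' @export
save_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("fallsense_svm_model: 1",
               sprintf("params: %s", paste(model$param_names, collapse = ",")),
               sprintf("gamma: %.17g", model$gamma),
               sprintf("cost: %.17g", model$cost),
               sprintf("bias: %.17g", model$bias),
               sprintf("scale_center: %s", if (is.null(model$scale_center))
                 "none" else paste(sprintf("%.17g", model$scale_center),
                                   collapse = ",")),
               sprintf("scale_range: %s", if (is.null(model$scale_range))
                 "none" else paste(sprintf("%.17g", model$scale_range),
                                   collapse = ",")),
               sprintf("nsv: %d", length(model$alphas))), con)
  for (j in seq_along(model$alphas))
    writeLines(paste(c(sprintf("%d", model$sv_labels[j]),
                       sprintf("%.17g", c(model$alphas[j],
                                          model$support_vectors[j, ]))),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 8 || !grepl("^fallsense_svm_model:", lines[1]))
    stop("not a fallsense SVM model file")
  version <- trimws(sub("^fallsense_svm_model:", "", lines[1]))
  if (version != "1") stop("unsupported model file version: ", version)
  field <- function(i, key) {
    if (!startsWith(lines[i], paste0(key, ":")))
      stop("malformed model file: expected '", key, "' on line ", i)
    trimws(sub(paste0("^", key, ":"), "", lines[i]))
  }
  params <- strsplit(field(2, "params"), ",")[[1]]
  gamma <- as.numeric(field(3, "gamma"))
  cost <- as.numeric(field(4, "cost"))
  bias <- as.numeric(field(5, "bias"))
  parse_vec <- function(s) if (identical(s, "none")) NULL
  else as.numeric(strsplit(s, ",")[[1]])
  scale_center <- parse_vec(field(6, "scale_center"))
  scale_range <- parse_vec(field(7, "scale_range"))
  nsv <- as.integer(field(8, "nsv"))
  if (length(lines) < 8 + nsv) stop("truncated model file: ",
                                    length(lines) - 8, " of ", nsv,
                                    " support vectors present")
  rows <- lapply(lines[8 + seq_len(nsv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  len <- lengths(rows)
  if (any(len != 2 + length(params))) stop("malformed support-vector line")
  mat <- do.call(rbind, rows)
  model <- list(support_vectors = mat[, -(1:2), drop = FALSE],
                alphas = mat[, 2], sv_labels = mat[, 1], bias = bias,
                gamma = gamma, cost = cost, param_names = params,
                scale_center = scale_center, scale_range = scale_range,
                iterations = NA_integer_)
  colnames(model$support_vectors) <- params
  if (any(is.na(mat))) stop("malformed model file: non-numeric entries")
  class(model) <- "fall_svm"
  model
}
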