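test_that("the RBF kernel evaluates its closed form", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 5.3), 1)
  expect_equal(rbf_kernel(c(1, 2), c(3, 9), 0), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), 5.3), exp(-5.3))
  expect_equal(rbf_kernel(c(0.3, -1), c(1.1, 0.2), 2),
               exp(-2 * (0.8^2 + 1.2^2)))
  expect_error(rbf_kernel(1:2, 1:3, 1), "dimension")
})

toy_frames <- function() {
  list(X = rbind(c(0, 0), c(0.3, 0), c(3, 3), c(3.2, 2.8)),
       D = c(-1, -1, 1, 1), params = c("a", "b"))
}

test_that("a separable toy problem is learned exactly", {
  fit <- svm_train(toy_frames(), gamma = 0.5, cost = 4.7)
  dec <- svm_decision(fit, toy_frames()$X)
  expect_equal(dec$label, toy_frames()$D)
  # margin condition on free support vectors
  tr_scores <- svm_decision(fit, fit$support_vectors)$score
  free <- fit$alphas < fit$cost - 1e-8
  expect_true(all(abs(tr_scores[free]) >= 1 - 1e-3))
  # dual feasibility
  expect_lt(abs(sum(fit$alphas * fit$sv_labels)), 1e-6)
  expect_true(all(fit$alphas > 0 & fit$alphas <= fit$cost + 1e-12))
})

test_that("training rejects degenerate inputs", {
  bad <- list(X = matrix(rnorm(10), 5), D = rep(1, 5), params = c("a", "b"))
  expect_error(svm_train(bad), "single class")
  bad2 <- list(X = matrix(rnorm(10), 5), D = c(1, -1, 2, 1, -1))
  expect_error(svm_train(bad2), "labels")
})

test_that("decision scores match an independent QP solution", {
  set.seed(55)
  worst <- 0
  for (k in 1:8) {
    prob <- tiny_svm_problem(m = sample(10:25, 1), n = sample(2:3, 1))
    fit <- svm_train(list(X = prob$X, D = prob$y), gamma = 5.3, cost = 4.7)
    probe <- matrix(rnorm(8 * ncol(prob$X)), 8)
    mine <- svm_decision(fit, probe)$score
    oracle <- qp_oracle_scores(prob$X, prob$y, probe, 5.3, 4.7)
    worst <- max(worst, max(abs(mine - oracle)))
  }
  expect_lt(worst, 1e-4)
})

test_that("KKT conditions hold on random training sets", {
  set.seed(66)
  for (k in 1:5) {
    prob <- tiny_svm_problem(m = 30, n = 2)
    C <- 4.7
    fit <- svm_train(list(X = prob$X, D = prob$y), gamma = 1.7, cost = C)
    sc <- svm_decision(fit, prob$X)$score
    marg <- prob$y * sc
    a <- rep(0, length(prob$y))
    # recover alphas by matching rows to stored support vectors
    for (j in seq_along(fit$alphas)) {
      i <- which(apply(prob$X, 1, function(r)
        all(abs(r - fit$support_vectors[j, ]) < 1e-12)))[1]
      a[i] <- fit$alphas[j]
    }
    tol <- 1e-3
    expect_true(all(marg[a < 1e-8] >= 1 - tol))          # non-SVs outside
    free <- a > 1e-8 & a < C - 1e-8
    expect_true(all(abs(marg[free] - 1) < tol))          # free SVs on margin
    expect_true(all(marg[a > C - 1e-8] <= 1 + tol))      # bounded SVs inside
  }
})

test_that("decision function is invariant to row permutation and duplication", {
  set.seed(77)
  prob <- tiny_svm_problem(m = 16, n = 2)
  prob$X[prob$y > 0, ] <- prob$X[prob$y > 0, ] + 2  # keep alphas interior
  probe <- matrix(rnorm(20), 10)
  fit <- svm_train(list(X = prob$X, D = prob$y), gamma = 0.8, cost = 4.7,
                   tol = 1e-9)
  base <- svm_decision(fit, probe)$score
  perm <- sample(length(prob$y))
  fit_p <- svm_train(list(X = prob$X[perm, ], D = prob$y[perm]),
                     gamma = 0.8, cost = 4.7, tol = 1e-9)
  expect_lt(max(abs(svm_decision(fit_p, probe)$score - base)), 1e-6)
  fit_d <- svm_train(list(X = rbind(prob$X, prob$X), D = c(prob$y, prob$y)),
                     gamma = 0.8, cost = 4.7, tol = 1e-9)
  expect_lt(max(abs(svm_decision(fit_d, probe)$score - base)), 1e-6)
})

test_that("classify_series equals sample-wise decision and checks params", {
  model <- small_model()
  p <- small_protocol()
  f <- p$features[[p$manifest$path[3]]][1:50, ]
  lab <- classify_series(model, f)
  X <- as.matrix(as.data.frame(f)[model$param_names])
  for (i in c(1, 10, 50))
    expect_equal(lab[i], svm_decision(model, X[i, ])$label)
  expect_error(classify_series(model, f, params = c("cv_fast")),
               "combination")
  empty <- f[0, ]
  expect_length(classify_series(model, empty), 0)
})

test_that("model files round-trip and reject malformed input", {
  model <- small_model()
  d <- withr::local_tempdir()
  path <- file.path(d, "m.txt")
  save_model(model, path)
  back <- load_model(path)
  set.seed(5)
  probe <- matrix(rnorm(40), 10)
  expect_equal(svm_decision(back, probe)$score,
               svm_decision(model, probe)$score, tolerance = 1e-12)
  expect_equal(back$gamma, model$gamma)
  expect_equal(back$param_names, model$param_names)

  lines <- readLines(path)
  writeLines(lines[1:10], file.path(d, "trunc.txt"))
  expect_error(load_model(file.path(d, "trunc.txt")), "truncated")
  writeLines(sub("fallsense_svm_model: 1", "fallsense_svm_model: 99",
                 lines), file.path(d, "ver.txt"))
  expect_error(load_model(file.path(d, "ver.txt")), "version")
  writeLines(c("garbage"), file.path(d, "junk.txt"))
  expect_error(load_model(file.path(d, "junk.txt")), "model file")
})

test_that("min-max scaling hook learns and applies ranges", {
  set.seed(88)
  prob <- tiny_svm_problem(m = 40, n = 2)
  prob$X[, 2] <- prob$X[, 2] * 100   # wildly different scale
  fit <- svm_train(list(X = prob$X, D = prob$y), gamma = 1, cost = 4.7,
                   scale = TRUE)
  expect_length(fit$scale_center, 2)
  expect_true(all(fit$support_vectors >= -1e-9 &
                    fit$support_vectors <= 1 + 1e-9))
  d <- withr::local_tempdir()
  save_model(fit, file.path(d, "s.txt"))
  back <- load_model(file.path(d, "s.txt"))
  probe <- matrix(rnorm(10) * 50, 5)
  expect_equal(svm_decision(back, probe)$score,
               svm_decision(fit, probe)$score, tolerance = 1e-12)
})
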