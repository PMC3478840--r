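# Independent QP oracle for the soft-margin dual, via scipy (SLSQP). The
# oracle shares no code with the package's SMO solver: it minimizes
# 0.5 a'Qa - e'a under 0 <= a <= C, y'a = 0 with a generic NLP solver and
# evaluates the decision function from its own solution.

qp_oracle_scores <- function(X, y, probe, gamma, C) {
  dir <- tempfile("qporacle")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::write.table(cbind(X, y), file.path(dir, "train.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(probe, file.path(dir, "probe.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  script <- file.path(dir, "qp.py")
  writeLines(c(
    "import sys, numpy as np",
    "from scipy.optimize import minimize",
    "d = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    "P = np.loadtxt(sys.argv[2], delimiter=',', ndmin=2)",
    "g = float(sys.argv[3]); C = float(sys.argv[4])",
    "X = d[:, :-1]; y = d[:, -1]; m = len(y)",
    "K = np.exp(-g * ((X[:, None, :] - X[None, :, :]) ** 2).sum(-1))",
    "Q = (y[:, None] * y[None, :]) * K",
    "r = minimize(lambda a: 0.5 * a @ Q @ a - a.sum(),",
    "             np.full(m, min(C, 1.0) / 2), jac=lambda a: Q @ a - 1,",
    "             bounds=[(0, C)] * m,",
    "             constraints=[{'type': 'eq', 'fun': lambda a: a @ y,",
    "                           'jac': lambda a: y}],",
    "             method='SLSQP', options={'maxiter': 5000, 'ftol': 1e-14})",
    "if not r.success: sys.exit('QP oracle failed: ' + r.message)",
    "a = r.x",
    "free = (a > 1e-6) & (a < C - 1e-6)",
    "fn_tr = (a * y) @ K",
    "b = np.mean(y[free] - fn_tr[free]) if free.any() else 0.0",
    "Kp = np.exp(-g * ((X[:, None, :] - P[None, :, :]) ** 2).sum(-1))",
    "np.savetxt(sys.argv[5], (a * y) @ Kp + b)"), script)
  out <- file.path(dir, "scores.txt")
  status <- system2("python", c(script, file.path(dir, "train.csv"),
                                file.path(dir, "probe.csv"),
                                format(gamma, digits = 17),
                                format(C, digits = 17), out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("QP oracle subprocess failed")
  scan(out, quiet = TRUE)
}

# random tiny two-class problem with both classes present
tiny_svm_problem <- function(m = 15, n = 2) {
  X <- matrix(rnorm(m * n), m)
  y <- sample(c(-1, 1), m, replace = TRUE)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  X[y > 0, 1] <- X[y > 0, 1] + 1.2   # some structure, still overlapping
  list(X = X, y = y)
}
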