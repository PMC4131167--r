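# Shared fixtures and independent oracles for the test suite.

make_pair_data <- function(p = 12, n = 40, seed = 1, rewire = 0.1) {
  if (p < 10) {
    # small fixtures: autoregressive-covariance Gaussians, slightly
    # different dependence strength per condition
    d <- withr::with_seed(seed, {
      s1 <- 0.4^abs(outer(1:p, 1:p, "-"))
      s2 <- 0.25^abs(outer(1:p, 1:p, "-"))
      kddn_data(MASS::mvrnorm(n, rep(0, p), s1),
                MASS::mvrnorm(n, rep(0, p), s2))
    })
    return(list(truth = NULL, data = standardize(d)))
  }
  truth <- perturb_network(simulate_gmrf_truth(p, seed = seed),
                           rewire_fraction = rewire, seed = seed + 1)
  list(truth = truth,
       data = standardize(sample_condition_data(truth, n, seed = seed + 2)))
}

# Independent objective for the two-coordinate subproblem.
g_pair <- function(b1, b2, c1, c2, a1, a2, w, l2) {
  0.5 * a1 * b1^2 - c1 * b1 + 0.5 * a2 * b2^2 - c2 * b2 +
    w * (abs(b1) + abs(b2)) + l2 * abs(b1 - b2)
}

# Two-stage 2-D grid-search oracle for the pair update: a coarse pass over
# [-span, span]^2 followed by a fine pass (step `fine`) in a window around
# the coarse minimizer. Valid for these convex objectives because the
# coarse minimizer is within one coarse step of the true one.
grid_oracle_pair <- function(c1, c2, a1, a2, w, l2, span = 2,
                             coarse = 0.005, fine = 1e-3) {
  stage <- function(b1s, b2s) {
    f1 <- 0.5 * a1 * b1s^2 - c1 * b1s + w * abs(b1s)
    f2 <- 0.5 * a2 * b2s^2 - c2 * b2s + w * abs(b2s)
    tot <- outer(f1, f2, "+") + l2 * abs(outer(b1s, b2s, "-"))
    k <- arrayInd(which.min(tot), dim(tot))
    list(b1 = b1s[k[1]], b2 = b2s[k[2]], g = tot[k])
  }
  s1 <- stage(seq(-span, span, by = coarse), seq(-span, span, by = coarse))
  win <- 4 * coarse
  stage(seq(s1$b1 - win, s1$b1 + win, by = fine),
        seq(s1$b2 - win, s1$b2 + win, by = fine))
}

# Generic convex-solver oracle for a whole node problem, run through the
# system python (scipy SLSQP on the smooth split reformulation
# b = u - v, b1 - b2 = s - r, all slacks non-negative, exact gradients).
# Returns the oracle's minimal objective value.
node_oracle_python <- function(X1, X2, i, w, lambda2) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  dir <- withr::local_tempdir()
  infile <- file.path(dir, "in.json")
  outfile <- file.path(dir, "out.json")
  script <- file.path(dir, "oracle.py")
  jsonlite::write_json(
    list(X1 = as.vector(X1), n1 = nrow(X1), X2 = as.vector(X2),
         n2 = nrow(X2), p = ncol(X1), i = i, w = w, lambda2 = lambda2),
    infile, digits = NA, auto_unbox = TRUE)
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import minimize",
    "d = json.load(open(sys.argv[1]))",
    "p = d['p']",
    "X1 = np.array(d['X1']).reshape(d['n1'], p, order='F')",
    "X2 = np.array(d['X2']).reshape(d['n2'], p, order='F')",
    "i = d['i'] - 1; w = np.array(d['w']); lam2 = d['lambda2']",
    "free = [j for j in range(p) if j != i]",
    "A1 = X1[:, free]; A2 = X2[:, free]; y1 = X1[:, i]; y2 = X2[:, i]",
    "m = len(free)",
    "def unpack(z):",
    "    u1, v1, u2, v2, s, r = z.reshape(6, m)",
    "    return u1 - v1, u2 - v2, z",
    "def fobj(z):",
    "    b1, b2, _ = unpack(z)",
    "    r1 = y1 - A1 @ b1; r2 = y2 - A2 @ b2",
    "    u1, v1, u2, v2, s, r = z.reshape(6, m)",
    "    return (0.5 * (r1 @ r1 + r2 @ r2) + w[free] @ (u1 + v1 + u2 + v2)",
    "            + lam2 * np.sum(s + r))",
    "def grad(z):",
    "    b1, b2, _ = unpack(z)",
    "    g1 = -A1.T @ (y1 - A1 @ b1); g2 = -A2.T @ (y2 - A2 @ b2)",
    "    wf = w[free]",
    "    return np.concatenate([g1 + wf, -g1 + wf, g2 + wf, -g2 + wf,",
    "                           lam2 * np.ones(m), lam2 * np.ones(m)])",
    "def cons_f(z):",
    "    u1, v1, u2, v2, s, r = z.reshape(6, m)",
    "    return (u1 - v1) - (u2 - v2) - (s - r)",
    "J = np.zeros((m, 6 * m))",
    "for k in range(m):",
    "    J[k, k] = 1; J[k, m + k] = -1; J[k, 2 * m + k] = -1",
    "    J[k, 3 * m + k] = 1; J[k, 4 * m + k] = -1; J[k, 5 * m + k] = 1",
    "res = minimize(fobj, np.zeros(6 * m), jac=grad, method='SLSQP',",
    "               bounds=[(0, None)] * (6 * m),",
    "               constraints=[{'type': 'eq', 'fun': cons_f,",
    "                             'jac': lambda z: J}],",
    "               options={'maxiter': 2000, 'ftol': 1e-14})",
    "json.dump({'objective': float(res.fun), 'ok': bool(res.success)},",
    "          open(sys.argv[2], 'w'))"
  ), script)
  status <- system2(py, c(script, infile, outfile), stdout = TRUE,
                    stderr = TRUE)
  stopifnot(file.exists(outfile))
  out <- jsonlite::read_json(outfile)
  stopifnot(isTRUE(out$ok))
  out$objective
}
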