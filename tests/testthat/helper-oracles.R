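# Independent oracle implementations used to cross-check the package's
# computational paths. These deliberately avoid the package's internals.

# trial-by-trial likelihood enumeration using only the exported primitive
# operations (independent of the C++ recursion)
nll_oracle <- function(params, trials) {
  tr <- trials[trials$abandoned == 0L & !is.na(trials$choice), ]
  tr <- tr[order(tr$session_id, tr$trial_index), ]
  qc <- 0; qi <- 0; prev <- "none"; nll <- 0
  for (i in seq_len(nrow(tr))) {
    x <- params$beta * (qc - qi) +
      params$stay * ((prev == "contra") - (prev == "ipsi"))
    p_contra <- 1 / (1 + exp(-x))
    p <- if (tr$choice[i] == "contra") p_contra else 1 - p_contra
    nll <- nll - log(p)
    if (tr$choice[i] == "contra") {
      qc <- qc + params$alpha * (tr$reward[i] - qc)
    } else {
      qi <- qi + params$alpha * (tr$reward[i] - qi)
    }
    prev <- tr$choice[i]
  }
  nll
}

# brute-force Benjamini-Hochberg from the step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# closed-form sandwich covariance for a dense design (independent algebra)
sandwich_oracle <- function(X, e, cl) {
  XtX_inv <- solve(crossprod(X))
  meat <- Reduce(`+`, lapply(unique(cl), function(g) {
    u <- crossprod(X[cl == g, , drop = FALSE], e[cl == g])
    u %*% t(u)
  }))
  G <- length(unique(cl)); n <- nrow(X); k <- ncol(X)
  G / (G - 1) * (n - 1) / (n - k) * XtX_inv %*% meat %*% XtX_inv
}

# small synthetic cohort shared across tests
make_small_cohort <- function(n_subjects = 4, trials_per_session = 150,
                              sessions = 2, seed = 11,
                              params = agent_params_default()) {
  set.seed(seed)
  tc <- task_config(trials_per_session = trials_per_session,
                    sessions_per_site = sessions)
  pl <- replicate(n_subjects, params, simplify = FALSE)
  list(trials = simulate_cohort(pl, tc), config = tc, params = pl)
}
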