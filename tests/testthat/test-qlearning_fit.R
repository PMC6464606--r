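test_that("negative log-likelihood matches analytic and enumeration oracles", {
  co <- make_small_cohort(n_subjects = 1, trials_per_session = 200,
                          sessions = 1)
  tr <- co$trials
  n <- sum(tr$abandoned == 0L)
  # uniform policy
  expect_equal(negloglik(agent_params(0.5, 0, 0), tr), n * log(2))

  # hand-computed two-trial oracle: alpha=.5, beta=1, stay=0,
  # choices (contra, contra), rewards (1, .): P1=.5, P2=logistic(.5)
  t2 <- tr[1:2, ]
  t2$choice <- c("contra", "contra"); t2$reward <- c(1L, 0L)
  t2$prev_choice <- c("none", "contra"); t2$abandoned <- 0L
  expect_equal(negloglik(agent_params(0.5, 1, 0), t2),
               -log(0.5) - log(plogis(0.5)))
  expect_equal(-log(0.5) - log(plogis(0.5)), 1.167224, tolerance = 1e-6)

  # independent trial-by-trial enumeration across random parameter sets
  set.seed(71)
  for (i in 1:8) {
    p <- agent_params(runif(1), runif(1, 0, 3), rnorm(1))
    expect_equal(negloglik(p, tr), nll_oracle(p, tr), tolerance = 1e-8)
  }
  expect_error(negloglik(agent_params(0.5, 1, 0), tr[integer(0), ]),
               "empty")
})

test_that("subject fits recover generating parameters and beat the truth", {
  set.seed(81)
  truth <- agent_params(0.6, 1.0, 0.9)
  tc <- task_config(trials_per_session = 250, sessions_per_site = 4)
  tr <- simulate_subject(truth, tc)
  fit <- fit_subject(tr)
  # fitted likelihood is at least as good as at the generating parameters
  expect_lte(-fit$loglik, negloglik(truth, tr) + 1e-6)
  expect_lt(abs(fit$params$alpha - truth$alpha), 0.15)
  expect_lt(abs(fit$params$beta - truth$beta), 0.35)
  expect_lt(abs(fit$params$stay - truth$stay), 0.3)
  expect_warning(fit_subject(tr[1:30, ]), "fewer than 50")
})

test_that("split-Rhat behaves at its analytic anchors", {
  x <- matrix(rep(sin(1:400), 2), ncol = 2)
  expect_equal(rhat(x), 1, tolerance = 0.01)
  # chains stuck at different constants: within-variance 0 -> Inf
  expect_equal(rhat(cbind(rep(1, 100), rep(2, 100))), Inf)
  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
  # iid normal draws at the study's post-warmup size mix essentially
  # perfectly
  set.seed(91)
  z <- matrix(rnorm(750 * 4), ncol = 4)
  expect_lt(rhat(z), 1.003)
})

test_that("Q trajectories satisfy their algebraic identities", {
  co <- make_small_cohort(n_subjects = 2, trials_per_session = 150,
                          sessions = 2)
  sp <- setNames(replicate(2, agent_params_default(), simplify = FALSE),
                 unique(co$trials$site_id))
  qt <- compute_q_trajectories(sp, co$trials)
  first_rows <- !duplicated(co$trials$site_id)
  expect_true(all(qt$dq_chosen[first_rows] == 0))
  # sign identity between frames on every completed trial
  comp <- co$trials$abandoned == 0L
  expect_equal(qt$dq_chosen[comp],
               ifelse(co$trials$choice[comp] == "contra", 1, -1) *
                 qt$dq_contra[comp])
  # standardised columns are mean 0 / SD 1 within site
  for (s in unique(qt$site_id)) {
    x <- qt$dq_chosen_std[qt$site_id == s]
    expect_equal(mean(x, na.rm = TRUE), 0, tolerance = 1e-10)
    expect_equal(sd(x, na.rm = TRUE), 1, tolerance = 1e-10)
  }
  # Q values bounded by the binary reward range
  expect_true(all(qt$q_contra >= 0 & qt$q_contra <= 1))
  expect_true(all(qt$q_ipsi >= 0 & qt$q_ipsi <= 1))
})

test_that("hierarchical backends agree and refuse degenerate input", {
  set.seed(101)
  tc <- task_config(trials_per_session = 250, sessions_per_site = 2)
  pl <- cohort_params(6)
  tr <- simulate_cohort(pl, tc)
  expect_error(fit_hierarchical(tr[tr$site_id == "m01", ]),
               ">= 2 subjects")

  map <- fit_hierarchical(tr, fit_config(method = "hierarchical_map"))
  mle <- fit_hierarchical(tr, fit_config(method = "per_subject_mle"))
  mcmc <- fit_hierarchical(tr, fit_config(method = "hierarchical_mcmc",
                                          rng_seed = 101))
  expect_true(all(diff(map$subject_dist_percentiles[, "alpha"]) >= 0))
  a_map <- vapply(map$subject_params, `[[`, numeric(1), "alpha")
  expect_true(all(a_map >= 0 & a_map <= 1))
  # the two hierarchical backends agree on subject point estimates
  for (par in c("alpha", "beta", "stay")) {
    v_map <- vapply(map$subject_params, `[[`, numeric(1), par)
    v_mc <- vapply(mcmc$subject_params, `[[`, numeric(1), par)
    tol <- if (par == "alpha") 0.05 else 0.1
    expect_lt(median(abs(v_map - v_mc)), tol)
  }
  expect_true(is.null(mle$rhat))
})

test_that("posterior-predictive simulation reproduces the stay fraction", {
  set.seed(111)
  tc <- task_config(trials_per_session = 250, sessions_per_site = 3)
  truth <- agent_params_default()
  tr <- simulate_subject(truth, tc)
  fit <- fit_subject(tr)
  sim <- simulate_subject(fit$params, tc)
  # within 3 percentage points
  expect_lt(abs(stay_fraction(sim) - stay_fraction(tr)), 0.03)
})
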