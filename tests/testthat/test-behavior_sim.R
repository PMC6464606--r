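test_that("block extension draws follow the shifted geometric law", {
  expect_error(draw_block_extension(1, 0), "p must be")
  expect_error(draw_block_extension(1, 1.2), "p must be")

  set.seed(1)
  expect_true(all(draw_block_extension(500, 1 - 1e-12) == 1))

  # closed-form pmf oracle at p = 0.5: P(k) = 0.5^k
  set.seed(2)
  x <- draw_block_extension(40000, 0.5)
  expect_true(all(x >= 1))
  emp <- tabulate(x)[1:3] / length(x)
  expect_equal(emp, c(0.5, 0.25, 0.125), tolerance = 0.05)

  # support starting at 1 gives mean 1/p
  set.seed(3)
  expect_equal(mean(draw_block_extension(2e5, 0.4)), 2.5, tolerance = 0.01)
})

test_that("q_update follows the delta rule", {
  expect_equal(q_update(0, 1, 1), 1)
  expect_equal(q_update(0.5, 0.5, 0.61), 0.5)
  expect_error(q_update(0, 1, 1.5), "alpha")
  # geometric convergence oracle: q_n = 1 - (1 - alpha)^n from q0 = 0, r = 1
  q <- 0
  for (i in 1:3) q <- q_update(q, 1, 0.5)
  expect_equal(q, 1 - 0.5^3)
  q <- 0
  for (i in 1:7) q <- q_update(q, 1, 0.3)
  expect_equal(q, 1 - 0.7^7)
})

test_that("choice probabilities are coherent softmax values", {
  p0 <- agent_params(0.5, 2, 0)
  expect_equal(choice_prob(0.4, 0.4, "none", p0), 0.5)

  # direct-evaluation oracle at the fitted group medians
  pm <- agent_params_default()
  expect_equal(choice_prob(0.7, 0.1, "contra", pm),
               plogis(0.990275 * 0.6 + 0.945385), tolerance = 1e-12)
  expect_equal(choice_prob(0.7, 0.1, "contra", pm), 0.8233993,
               tolerance = 1e-6)

  # two-action probabilities sum to one under frame swap
  p1 <- agent_params(0.3, 1.4, 0.6)
  pc <- choice_prob(0.8, 0.2, "ipsi", p1)
  pi_ <- choice_prob(0.2, 0.8, "contra", p1)  # mirrored orientation
  expect_equal(pc + pi_, 1)

  # stay strictly increases repeat probability; beta sharpens preference
  expect_gt(choice_prob(0.5, 0.5, "contra", agent_params(0.5, 1, 2)),
            choice_prob(0.5, 0.5, "contra", agent_params(0.5, 1, 1)))
  expect_gt(choice_prob(0.7, 0.2, "none", agent_params(0.5, 5, 0)),
            choice_prob(0.7, 0.2, "none", agent_params(0.5, 1, 0)))
  # stay -> +Inf with prev = ipsi forces ipsi
  expect_lt(choice_prob(0.9, 0.1, "ipsi", agent_params(0.5, 1, 50)), 1e-10)
})

test_that("simulated sessions respect the task's block and timing rules", {
  set.seed(21)
  tc <- task_config(trials_per_session = 600, sessions_per_site = 1)
  res <- simulate_session(agent_params_default(), tc)
  tr <- res$trials

  # completed blocks accumulate at least 10 rewards
  nb <- max(tr$block_id)
  for (b in seq_len(nb - 1)) {
    expect_gte(sum(tr$reward[tr$block_id == b], na.rm = TRUE),
               tc$min_rewarded_per_block)
  }
  # high side alternates between consecutive blocks
  sides <- tapply(tr$high_side, tr$block_id, function(x) unique(x))
  expect_true(all(sides[-1] != sides[-length(sides)]))

  # event ordering and latency bounds on non-abandoned trials
  ok <- tr$abandoned == 0L
  expect_true(all(tr$t_nose_poke[ok] < tr$t_lever_present[ok]))
  expect_true(all(tr$t_lever_present[ok] < tr$t_lever_press[ok]))
  expect_true(all(tr$t_lever_press[ok] < tr$t_outcome[ok]))
  expect_true(all(tr$press_latency[ok] > 0 &
                    tr$press_latency[ok] <= tc$press_deadline))
  expect_equal(tr$press_latency[ok],
               tr$t_lever_press[ok] - tr$t_lever_present[ok])

  # prev fields equal the preceding completed trial's choice/reward
  comp <- which(ok)
  for (i in comp[-1]) {
    prev <- max(comp[comp < i])
    expect_identical(tr$prev_choice[i], tr$choice[prev])
    expect_identical(tr$prev_reward[i], tr$reward[prev])
  }
})

test_that("near-certain rewards make block length exactly 10 plus the draw", {
  # with both levers rewarding almost surely, every trial is rewarded, so
  # a block ends exactly min_rewarded trials plus the geometric extension in
  set.seed(5)
  tc <- task_config(p_high = 1 - 1e-9, p_low = 1 - 2e-9,
                    trials_per_session = 400, sessions_per_site = 1)
  res <- simulate_session(agent_params(0.5, 0, 0), tc)
  tr <- res$trials
  lens <- as.numeric(table(tr$block_id))
  lens <- lens[-length(lens)]  # last block truncated by session end
  expect_true(all(lens >= tc$min_rewarded_per_block + 1))
  expect_true(all(tr$reward[tr$abandoned == 0L] == 1L))
})

test_that("indifferent agents choose each side half the time", {
  set.seed(31)
  tc <- task_config(trials_per_session = 800, sessions_per_site = 1)
  res <- simulate_session(agent_params(0.5, 0, 0), tc)
  frac <- mean(res$trials$choice == "contra", na.rm = TRUE)
  expect_equal(frac, 0.5, tolerance = 0.06)
})

test_that("reversal-aligned choice curve decays after the switch", {
  set.seed(41)
  tc <- task_config(trials_per_session = 400, sessions_per_site = 2)
  tr <- simulate_cohort(replicate(5, agent_params_default(),
                                  simplify = FALSE), tc)
  cv <- reversal_aligned_choice_curve(tr, window = 10)
  expect_equal(nrow(cv), 21)
  expect_gt(cv$p_pre_high[cv$lag == -1], 0.5)
  # monotone-decreasing trend over lags 0..10
  post <- cv$p_pre_high[cv$lag >= 0]
  expect_lt(coef(lm(post ~ seq_along(post)))[2], 0)
  expect_lt(mean(cv$p_pre_high[cv$lag >= 5]),
            mean(cv$p_pre_high[cv$lag < 0]))
  expect_error(reversal_aligned_choice_curve(tr[tr$block_id == 1 &
                                                  tr$session_id == 1, ]),
               "no block switches")
})

test_that("stay fraction is stable across seeds", {
  fr <- vapply(1:20, function(s) {
    set.seed(100 + s)
    tc <- task_config(trials_per_session = 400, sessions_per_site = 2)
    stay_fraction(simulate_subject(agent_params_default(), tc))
  }, numeric(1))
  expect_lt(sd(fr), 0.02)
})

test_that("trial tables round-trip losslessly through CSV", {
  set.seed(51)
  tc <- task_config(trials_per_session = 60, sessions_per_site = 2)
  tr <- simulate_subject(agent_params_default(), tc)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back, tr, ignore_attr = TRUE)
})
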