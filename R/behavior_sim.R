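#' Task configuration for the probabilistic reversal-learning task
#'
#' Defaults reproduce the operant task the analysis assumes: two levers with
#' 70% / 10% reward probability, the identity of the high-probability lever
#' reversing in a pseudorandom block schedule (each block lasts until at least
#' `min_rewarded_per_block` rewarded trials have occurred, plus a random
#' number of extra trials drawn from a Geometric distribution with success
#' probability `block_extension_p` on support 1, 2, ...), a 0-1 s jittered
#' delay (0.1 s grid) before lever presentation and before the outcome, a
#' 10 s press deadline after which the trial is abandoned, and a 3 s
#' inter-trial delay. Photometry is assumed sampled at 15 Hz.
#'
#' @param p_high,p_low reward probabilities of the high/low lever.
#' @param min_rewarded_per_block rewarded trials required before the block
#'   extension countdown starts.
#' @param block_extension_p success probability of the geometric block
#'   extension (support starts at 1, so the mean is `1/p`).
#' @param sampling_rate photometry sampling rate in Hz.
#' @param press_deadline seconds allowed for the lever press.
#' @param event_jitter_max,event_jitter_step jittered delay range and grid (s).
#' @param inter_trial_delay seconds between outcome and the next trial.
#' @param trials_per_session,sessions_per_site synthetic session sizing.
#' @param press_latency_median,press_latency_sdlog log-normal press-latency
#'   parameters (median in seconds, log-scale SD).
#' @param q_reset_per_session reset Q values (and the stay indicator) at each
#'   session boundary instead of only once per subject record.
#' @return a `task_config` list.
#' @export
task_config <- function(p_high = 0.70, p_low = 0.10,
                        min_rewarded_per_block = 10L,
                        block_extension_p = 0.4,
                        sampling_rate = 15,
                        press_deadline = 10,
                        event_jitter_max = 1.0,
                        event_jitter_step = 0.1,
                        inter_trial_delay = 3,
                        trials_per_session = 250L,
                        sessions_per_site = 4L,
                        press_latency_median = 0.5,
                        press_latency_sdlog = 0.6,
                        q_reset_per_session = FALSE) {
  if (!(p_low > 0 && p_low < p_high && p_high < 1))
    stop("require 0 < p_low < p_high < 1", call. = FALSE)
  if (!(block_extension_p > 0 && block_extension_p < 1))
    stop("block_extension_p must be in (0,1)", call. = FALSE)
  if (min_rewarded_per_block < 1)
    stop("min_rewarded_per_block must be >= 1", call. = FALSE)
  if (event_jitter_max < 0 || event_jitter_step <= 0 ||
      event_jitter_max > 0 &&
      abs(event_jitter_max / event_jitter_step -
          round(event_jitter_max / event_jitter_step)) > 1e-8)
    stop("event_jitter_max must be a multiple of event_jitter_step",
         call. = FALSE)
  structure(list(
    p_high = p_high, p_low = p_low,
    min_rewarded_per_block = as.integer(min_rewarded_per_block),
    block_extension_p = block_extension_p,
    sampling_rate = sampling_rate,
    press_deadline = press_deadline,
    event_jitter_max = event_jitter_max,
    event_jitter_step = event_jitter_step,
    inter_trial_delay = inter_trial_delay,
    trials_per_session = as.integer(trials_per_session),
    sessions_per_site = as.integer(sessions_per_site),
    press_latency_median = press_latency_median,
    press_latency_sdlog = press_latency_sdlog,
    q_reset_per_session = isTRUE(q_reset_per_session)
  ), class = "task_config")
}

#' Q-learning agent parameters
#'
#' @param alpha learning rate in \[0,1\].
#' @param beta softmax inverse temperature, >= 0.
#' @param stay additive bonus for repeating the previous choice (real).
#' @return an `agent_params` list.
#' @export
agent_params <- function(alpha, beta, stay) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0,1]", call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("beta must be >= 0", call. = FALSE)
  if (!is.finite(stay)) stop("stay must be finite", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, stay = stay),
            class = "agent_params")
}

#' Group-median agent parameters estimated from mice on this task
#'
#' Medians of the group-level posterior for the hierarchical Q-learning model
#' fitted to mouse behavior on the reversal task (learning rate 0.612,
#' inverse temperature 0.990, stay bonus 0.945).
#'
#' @return an [agent_params()] object.
#' @export
agent_params_default <- function() {
  agent_params(alpha = 0.611693, beta = 0.990275, stay = 0.945385)
}

#' Draw block-extension lengths
#'
#' Geometric draws on support 1, 2, ... with mean `1/p` (so the task default
#' `p = 0.4` gives mean 2.5 extra trials per block).
#'
#' @param n number of draws.
#' @param p success probability in (0,1).
#' @return integer vector of draws, all >= 1.
#' @export
draw_block_extension <- function(n = 1L, p = 0.4) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("p must be in (0,1)", call. = FALSE)
  rgeom(n, p) + 1L
}

#' Delta-rule update of the chosen action's value
#'
#' @param q_chosen current value of the chosen action.
#' @param reward outcome in \{0,1\} (any real reward is accepted).
#' @param alpha learning rate in \[0,1\].
#' @return updated value `q + alpha * (reward - q)`.
#' @export
q_update <- function(q_chosen, reward, alpha) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("alpha must be in [0,1]", call. = FALSE)
  q_chosen + alpha * (reward - q_chosen)
}

#' Softmax probability of choosing the contralateral lever
#'
#' `P(contra) = logistic(beta * (q_contra - q_ipsi) + stay * (I(contra, prev)
#' - I(ipsi, prev)))`, where `I` indicates repetition of the previous choice.
#' On the first trial (`prev_choice = "none"`) the stay term contributes
#' nothing to either action. Vectorised over trials.
#'
#' @param q_contra,q_ipsi action values.
#' @param prev_choice `"contra"`, `"ipsi"` or `"none"`.
#' @param params an [agent_params()] object.
#' @return probability of choosing contra.
#' @export
choice_prob <- function(q_contra, q_ipsi, prev_choice, params) {
  stay_sign <- ifelse(prev_choice == "contra", 1,
                      ifelse(prev_choice == "ipsi", -1, 0))
  plogis(params$beta * (q_contra - q_ipsi) + params$stay * stay_sign)
}

draw_jitter <- function(n, config) {
  # uniform on the 0.1 s grid; 0 excluded so event times stay strictly
  # ordered within a trial
  grid <- seq(config$event_jitter_step, config$event_jitter_max,
              by = config$event_jitter_step)
  grid[sample.int(length(grid), n, replace = TRUE)]
}

#' Simulate one session of the reversal task
#'
#' Simulates a Q-learning agent with a stay bias through one session of the
#' block-reversal task, producing a tidy trial table with event timestamps
#' (seconds from session start). Q values and the stay indicator carry over
#' from `state` so multi-session subject records can be concatenated; with
#' `state = NULL` they are initialised to zero / none.
#'
#' @param params an [agent_params()] object.
#' @param config a [task_config()] object.
#' @param site_id,session_id identifiers stamped into the table.
#' @param state internal carry-over state from the previous session.
#' @return list with `trials` (data.frame, one row per trial),
#'   `block_boundaries` (trial indices starting a new block) and `state`.
#' @export
simulate_session <- function(params, config, site_id = "site1",
                             session_id = 1L, state = NULL) {
  n <- config$trials_per_session
  if (is.null(n) || n <= 0)
    stop("trials_per_session must be positive", call. = FALSE)
  if (is.null(state)) {
    state <- list(qc = 0, qi = 0, prev_choice = "none", prev_reward = NA)
  }
  qc <- state$qc; qi <- state$qi
  prev_choice <- state$prev_choice; prev_reward <- state$prev_reward

  high_side <- sample(c("contra", "ipsi"), 1L)
  block_id <- 1L
  rewarded_in_block <- 0L
  switch_after <- NA_integer_   # trial index after which the block switches
  trials_in_block <- 0L

  cols <- list(
    site_id = character(n), session_id = integer(n), trial_index = integer(n),
    block_id = integer(n), high_side = character(n), choice = character(n),
    reward = integer(n), prev_choice = character(n), prev_reward = integer(n),
    t_nose_poke = numeric(n), t_lever_present = numeric(n),
    t_lever_press = numeric(n), t_outcome = numeric(n),
    press_latency = numeric(n), abandoned = integer(n)
  )
  t_cursor <- 0
  block_boundaries <- 1L

  # per-trial randomness drawn up front (the choice/reward draws remain
  # sequential because they depend on the evolving Q values)
  jit1 <- draw_jitter(n, config)
  jit2 <- draw_jitter(n, config)
  jit3 <- draw_jitter(n, config)
  lat <- rlnorm(n, log(config$press_latency_median),
                config$press_latency_sdlog)
  u_choice <- runif(n)
  u_reward <- runif(n)

  for (i in seq_len(n)) {
    trials_in_block <- trials_in_block + 1L
    t_nose <- t_cursor + jit1[i]
    t_present <- t_nose + jit2[i]
    latency <- lat[i]
    abandoned <- latency > config$press_deadline

    cols$site_id[i] <- site_id
    cols$session_id[i] <- as.integer(session_id)
    cols$trial_index[i] <- i
    cols$block_id[i] <- block_id
    cols$high_side[i] <- high_side
    cols$prev_choice[i] <- prev_choice
    cols$prev_reward[i] <- if (is.na(prev_reward)) NA_integer_
                           else as.integer(prev_reward)
    cols$t_nose_poke[i] <- t_nose
    cols$t_lever_present[i] <- t_present

    if (abandoned) {
      cols$choice[i] <- NA_character_
      cols$reward[i] <- NA_integer_
      cols$t_lever_press[i] <- NA_real_
      cols$t_outcome[i] <- NA_real_
      cols$press_latency[i] <- NA_real_
      cols$abandoned[i] <- 1L
      t_cursor <- t_present + config$press_deadline + config$inter_trial_delay
    } else {
      p_contra <- choice_prob(qc, qi, prev_choice, params)
      choice <- if (u_choice[i] < p_contra) "contra" else "ipsi"
      p_rew <- if (choice == high_side) config$p_high else config$p_low
      reward <- as.integer(u_reward[i] < p_rew)
      t_press <- t_present + latency
      t_outcome <- t_press + jit3[i]

      cols$choice[i] <- choice
      cols$reward[i] <- reward
      cols$t_lever_press[i] <- t_press
      cols$t_outcome[i] <- t_outcome
      cols$press_latency[i] <- latency
      cols$abandoned[i] <- 0L

      if (choice == "contra") qc <- q_update(qc, reward, params$alpha)
      else                    qi <- q_update(qi, reward, params$alpha)
      prev_choice <- choice
      prev_reward <- reward
      rewarded_in_block <- rewarded_in_block + reward
      t_cursor <- t_outcome + config$inter_trial_delay
    }

    if (is.na(switch_after) &&
        rewarded_in_block >= config$min_rewarded_per_block) {
      switch_after <- trials_in_block +
        draw_block_extension(1L, config$block_extension_p)
    }
    if (!is.na(switch_after) && trials_in_block >= switch_after && i < n) {
      high_side <- if (high_side == "contra") "ipsi" else "contra"
      block_id <- block_id + 1L
      rewarded_in_block <- 0L
      trials_in_block <- 0L
      switch_after <- NA_integer_
      block_boundaries <- c(block_boundaries, i + 1L)
    }
  }

  trials <- as.data.frame(cols, stringsAsFactors = FALSE)
  list(trials = trials, block_boundaries = block_boundaries,
       state = list(qc = qc, qi = qi, prev_choice = prev_choice,
                    prev_reward = prev_reward))
}

#' Simulate a subject's multi-session record
#'
#' Sessions are simulated sequentially with Q values and the stay indicator
#' carried across session boundaries (the analyses concatenate sessions per
#' recording site), unless `config$q_reset_per_session` is set.
#'
#' @inheritParams simulate_session
#' @param n_sessions number of sessions (defaults to
#'   `config$sessions_per_site`).
#' @return data.frame of trials across all sessions.
#' @export
simulate_subject <- function(params, config, site_id = "site1",
                             n_sessions = config$sessions_per_site) {
  state <- NULL
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    res <- simulate_session(params, config, site_id = site_id,
                            session_id = s, state = state)
    state <- if (config$q_reset_per_session) NULL else res$state
    out[[s]] <- res$trials
  }
  do.call(rbind, out)
}

#' Draw a cohort of agent parameter sets around group medians
#'
#' Subject-level parameters are drawn from Gaussian distributions on the
#' unconstrained scales (logit for alpha, log for beta, identity for stay)
#' centred at the supplied group medians, mirroring the hierarchical model's
#' random-effects structure.
#'
#' @param n_subjects cohort size.
#' @param medians an [agent_params()] object giving the group medians.
#' @param sd_unconstrained length-3 SDs on the unconstrained scales.
#' @return list of [agent_params()] objects.
#' @export
cohort_params <- function(n_subjects, medians = agent_params_default(),
                          sd_unconstrained = c(0.20, 0.15, 0.15)) {
  mu <- c(qlogis(medians$alpha), log(medians$beta), medians$stay)
  lapply(seq_len(n_subjects), function(j) {
    th <- rnorm(3, mu, sd_unconstrained)
    agent_params(plogis(th[1]), exp(th[2]), th[3])
  })
}

#' Simulate a cohort of subjects
#'
#' @param params_list list of [agent_params()] (e.g. from [cohort_params()]).
#' @param config a [task_config()] object.
#' @param site_prefix site identifiers are `paste0(site_prefix, j)`.
#' @return data.frame of trials for all subjects.
#' @export
simulate_cohort <- function(params_list, config, site_prefix = "m") {
  out <- lapply(seq_along(params_list), function(j) {
    simulate_subject(params_list[[j]], config,
                     site_id = sprintf("%s%02d", site_prefix, j))
  })
  do.call(rbind, out)
}

#' Reversal-aligned choice curve
#'
#' Probability of choosing the lever that was the high-probability lever
#' before a block switch, as a function of trial lag around the switch
#' (within-session switches only). Averaged within site, then mean and
#' standard error across sites.
#'
#' @param trials trial table from the simulator (or imported).
#' @param window number of trials before/after the switch.
#' @return data.frame with `lag`, `p_pre_high`, `se`, `n_sites`.
#' @export
reversal_aligned_choice_curve <- function(trials, window = 10L) {
  lags <- -window:window
  per_site <- list()
  for (site in unique(trials$site_id)) {
    st <- trials[trials$site_id == site, ]
    acc <- matrix(NA_real_, nrow = 0, ncol = length(lags))
    for (ses in unique(st$session_id)) {
      ss <- st[st$session_id == ses, ]
      switches <- which(diff(ss$block_id) == 1L) + 1L  # first trial of block
      for (sw in switches) {
        pre_high <- ss$high_side[sw - 1L]
        idx <- sw + lags
        ok <- idx >= 1L & idx <= nrow(ss)
        row <- rep(NA_real_, length(lags))
        row[ok] <- as.numeric(ss$choice[idx[ok]] == pre_high)
        acc <- rbind(acc, row)
      }
    }
    if (nrow(acc) > 0)
      per_site[[site]] <- colMeans(acc, na.rm = TRUE)
  }
  if (length(per_site) == 0)
    stop("no block switches found", call. = FALSE)
  m <- do.call(rbind, per_site)
  data.frame(
    lag = lags,
    p_pre_high = colMeans(m, na.rm = TRUE),
    se = apply(m, 2, function(x) sd(x, na.rm = TRUE) /
                 sqrt(sum(is.finite(x)))),
    n_sites = nrow(m)
  )
}

#' Fraction of stay trials
#'
#' Proportion of completed, non-first trials on which the choice repeats the
#' previous completed trial's choice.
#'
#' @param trials trial table.
#' @return scalar in \[0,1\].
#' @export
stay_fraction <- function(trials) {
  ok <- trials$abandoned == 0L & trials$prev_choice != "none" &
    !is.na(trials$choice)
  mean(trials$choice[ok] == trials$prev_choice[ok])
}
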