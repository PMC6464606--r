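#' Fitting configuration for the hierarchical Q-learning model
#'
#' Defaults mirror the original sampling setup: 4 chains of 1000 iterations
#' with the first 250 discarded as warmup. The MCMC backend here is an
#' adaptive-free slice sampler (stepping-out with shrinkage) over subject
#' parameters on unconstrained scales, with conjugate Gibbs updates for the
#' group means and slice updates for the group SDs; `target_accept` is kept
#' for API compatibility with step-size-adapting samplers and is ignored.
#'
#' @param method `"hierarchical_mcmc"`, `"hierarchical_map"` or
#'   `"per_subject_mle"`.
#' @param n_chains,n_iter,n_warmup MCMC schedule; `n_warmup < n_iter`.
#' @param target_accept unused by the slice sampler.
#' @param prior_mean_sd SD of the Normal(0, .) prior on group means
#'   (unconstrained scales).
#' @param prior_sigma_sd scale of the half-Normal prior on group SDs.
#' @param rng_seed integer master seed.
#' @return a `fit_config` list.
#' @export
fit_config <- function(method = c("hierarchical_mcmc", "hierarchical_map",
                                  "per_subject_mle"),
                       n_chains = 4L, n_iter = 1000L, n_warmup = 250L,
                       target_accept = 0.99,
                       prior_mean_sd = 1.5, prior_sigma_sd = 1.0,
                       rng_seed = 1L) {
  method <- match.arg(method)
  if (n_warmup >= n_iter) stop("n_warmup must be < n_iter", call. = FALSE)
  if (method == "hierarchical_mcmc" && n_chains < 2)
    stop("n_chains must be >= 2 for MCMC", call. = FALSE)
  structure(list(method = method, n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter), n_warmup = as.integer(n_warmup),
                 target_accept = target_accept,
                 prior_mean_sd = prior_mean_sd,
                 prior_sigma_sd = prior_sigma_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "fit_config")
}

# Encode a (possibly multi-subject) trial table for the C++ likelihood.
encode_trials <- function(trials, q_reset_per_session = FALSE) {
  keep <- trials$abandoned == 0L & !is.na(trials$choice)
  tr <- trials[keep, ]
  ord <- order(tr$site_id, tr$session_id, tr$trial_index)
  tr <- tr[ord, ]
  sites <- unique(tr$site_id)
  choice <- as.integer(tr$choice == "contra")
  reward <- as.integer(tr$reward)
  new_site <- c(TRUE, tr$site_id[-1] != tr$site_id[-nrow(tr)])
  if (q_reset_per_session) {
    new_ses <- c(TRUE, tr$session_id[-1] != tr$session_id[-nrow(tr)])
    reset <- as.integer(new_site | new_ses)
  } else reset <- as.integer(new_site)
  start <- which(new_site) - 1L
  len <- diff(c(start, nrow(tr)))
  list(sites = sites, choice = choice, reward = reward, reset = reset,
       start = as.integer(start), len = as.integer(len))
}

#' Negative log-likelihood of one subject's choices
#'
#' Forward-simulates the Q recursion on the observed choices and rewards and
#' accumulates `-log P(choice_t)` under the softmax-with-stay policy.
#' Abandoned trials are excluded; Q values and the stay indicator start at
#' zero / none at the head of the record (and at session boundaries if
#' `q_reset_per_session`).
#'
#' @param params an [agent_params()] object.
#' @param trials one subject's trial table.
#' @param q_reset_per_session reset at session boundaries.
#' @return scalar negative log-likelihood.
#' @export
negloglik <- function(params, trials, q_reset_per_session = FALSE) {
  if (nrow(trials) == 0) stop("empty trial list", call. = FALSE)
  if (length(unique(trials$site_id)) != 1)
    stop("negloglik expects a single subject's trials", call. = FALSE)
  enc <- encode_trials(trials, q_reset_per_session)
  .nll_qlearn_cpp(params$alpha, params$beta, params$stay,
                  enc$choice, enc$reward, enc$reset)
}

# unconstrained <-> natural
theta_to_params <- function(th) {
  agent_params(plogis(th[1]), exp(th[2]), th[3])
}
params_to_theta <- function(p) c(qlogis(p$alpha), log(p$beta), p$stay)

nll_theta <- function(th, enc_choice, enc_reward, enc_reset) {
  .nll_qlearn_cpp(plogis(th[1]), exp(th[2]), th[3],
                  enc_choice, enc_reward, enc_reset)
}

#' Maximum-likelihood fit for a single subject
#'
#' Optimises the likelihood over (alpha, beta, stay) on unconstrained scales
#' (logit alpha, log beta) with L-BFGS-B from multiple starts. An optional
#' Gaussian penalty on the unconstrained scale (`prior_mu`, `prior_sd`)
#' turns this into a MAP estimate, which also guards degenerate,
#' perfectly-separable choice sequences.
#'
#' @param trials one subject's trial table.
#' @param n_starts number of optimiser starts (first is deterministic).
#' @param prior_mu,prior_sd optional Gaussian penalty (length 3) on the
#'   unconstrained scale; `NULL` for pure MLE.
#' @param q_reset_per_session see [negloglik()].
#' @return list with `params` ([agent_params()]), `loglik`, `theta`
#'   (unconstrained), `convergence`.
#' @export
fit_subject <- function(trials, n_starts = 3L, prior_mu = NULL,
                        prior_sd = NULL, q_reset_per_session = FALSE) {
  enc <- encode_trials(trials, q_reset_per_session)
  if (length(enc$choice) < 50)
    warning("fewer than 50 trials; estimates may be unstable", call. = FALSE)
  obj <- function(th) {
    v <- nll_theta(th, enc$choice, enc$reward, enc$reset)
    if (!is.null(prior_mu))
      v <- v - sum(dnorm(th, prior_mu, prior_sd, log = TRUE))
    v
  }
  starts <- list(c(0, 0, 0))
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1L))
      starts[[i + 1L]] <- rnorm(3, c(0, 0, 0.5), c(1.0, 0.7, 0.7))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = c(-8, -8, -10), upper = c(8, 5, 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("optimiser failed from every start", call. = FALSE)
  list(params = theta_to_params(best$par),
       loglik = -nll_theta(best$par, enc$choice, enc$reward, enc$reset),
       theta = best$par, convergence = best$convergence)
}

#' Split-chain potential scale reduction statistic
#'
#' Each chain is split in half; Rhat is computed from the between- and
#' within-half variances. Values near 1 indicate convergence.
#'
#' @param draws iterations x chains matrix of posterior draws for one
#'   parameter.
#' @return scalar Rhat (>= 1 up to floating point).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("need >= 2 chains", call. = FALSE)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  B <- nn * var(means)
  W <- mean(apply(sub, 2, var))
  if (W <= 0) return(Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# univariate slice sampler (stepping out + shrinkage) for the group SDs
slice1 <- function(x0, logf, w = 0.5, max_step = 30L) {
  lp0 <- logf(x0)
  logy <- lp0 - rexp(1)
  u <- runif(1)
  L <- x0 - w * u; R <- L + w
  j <- floor(runif(1) * max_step); k <- max_step - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

#' Hierarchical fit of the Q-learning model across subjects
#'
#' Subject-level parameters (logit alpha, log beta, stay) are modelled as
#' Gaussian draws from group-level distributions on the unconstrained
#' scales. Backends: MCMC (slice-within-Gibbs; default), MAP-EM with Laplace
#' variance propagation, or independent per-subject MLE.
#'
#' @param trials multi-subject trial table (subjects keyed by `site_id`).
#' @param config a [fit_config()] object.
#' @param q_reset_per_session see [negloglik()].
#' @return a `fit_result` list: `subject_params` (list of [agent_params()]
#'   per subject, posterior medians for MCMC), `group_percentiles` (3 x 3
#'   matrix, 25/50/75th percentiles of the transformed group-mean
#'   parameters), `subject_dist_percentiles` (same layout, percentiles of
#'   the implied subject-level distribution), `rhat` (named vector; MCMC
#'   only), `loglik`, `samples` (MCMC only), `method`.
#' @export
fit_hierarchical <- function(trials, config = fit_config(),
                             q_reset_per_session = FALSE) {
  enc <- encode_trials(trials, q_reset_per_session)
  J <- length(enc$sites)
  if (J < 2) stop("hierarchical fit needs >= 2 subjects", call. = FALSE)
  switch(config$method,
    hierarchical_mcmc = fit_mcmc(enc, config),
    hierarchical_map = fit_map_em(enc, config),
    per_subject_mle = fit_mle_cohort(enc, config))
}

mle_by_subject <- function(enc, prior_mu = NULL, prior_sd = NULL) {
  J <- length(enc$sites)
  th <- matrix(0, J, 3)
  for (j in seq_len(J)) {
    rng <- (enc$start[j] + 1L):(enc$start[j] + enc$len[j])
    obj <- function(t3) {
      v <- nll_theta(t3, enc$choice[rng], enc$reward[rng], enc$reset[rng])
      if (!is.null(prior_mu))
        v <- v - sum(dnorm(t3, prior_mu, prior_sd, log = TRUE))
      v
    }
    fit <- optim(c(0, 0, 0.5), obj, method = "L-BFGS-B",
                 lower = c(-8, -8, -10), upper = c(8, 5, 10))
    th[j, ] <- fit$par
  }
  th
}

total_loglik <- function(enc, th) {
  -sum(.nll_qlearn_multi_cpp(plogis(th[, 1]), exp(th[, 2]), th[, 3],
                             enc$choice, enc$reward, enc$reset,
                             enc$start, enc$len))
}

pct_names <- c("p25", "p50", "p75")
par_names <- c("alpha", "beta", "stay")

transform_cols <- function(m) {
  cbind(plogis(m[, 1]), exp(m[, 2]), m[, 3])
}

fit_mle_cohort <- function(enc, config) {
  th <- mle_by_subject(enc)
  nat <- transform_cols(th)
  gp <- apply(nat, 2, quantile, probs = c(0.25, 0.5, 0.75))
  dimnames(gp) <- list(pct_names, par_names)
  structure(list(
    subject_params = setNames(lapply(seq_len(nrow(th)), function(j)
      theta_to_params(th[j, ])), enc$sites),
    group_percentiles = gp, subject_dist_percentiles = gp,
    rhat = NULL, loglik = total_loglik(enc, th), samples = NULL,
    method = "per_subject_mle"), class = "fit_result")
}

fit_map_em <- function(enc, config, n_em = 40L, tol = 1e-4) {
  J <- length(enc$sites)
  mu <- c(0, 0, 0.5); sigma <- c(0.5, 0.5, 0.5)
  th <- mle_by_subject(enc, prior_mu = mu, prior_sd = sigma)
  for (it in seq_len(n_em)) {
    vj <- matrix(0, J, 3)
    for (j in seq_len(J)) {
      rng <- (enc$start[j] + 1L):(enc$start[j] + enc$len[j])
      obj <- function(t3)
        nll_theta(t3, enc$choice[rng], enc$reward[rng], enc$reset[rng]) -
          sum(dnorm(t3, mu, sigma, log = TRUE))
      fit <- optim(th[j, ], obj, method = "L-BFGS-B",
                   lower = c(-8, -8, -10), upper = c(8, 5, 10))
      th[j, ] <- fit$par
      H <- tryCatch(stats::optimHess(fit$par, obj), error = function(e) NULL)
      vj[j, ] <- if (is.null(H)) 0 else {
        d <- tryCatch(diag(solve(H)), error = function(e) rep(0, 3))
        pmax(pmin(d, 1), 0)
      }
    }
    mu_new <- (colSums(th) / sigma^2) /
      (J / sigma^2 + 1 / config$prior_mean_sd^2)
    s2 <- (colSums(sweep(th, 2, mu_new)^2 + vj) + 0.02) / (J + 1)
    sigma_new <- pmax(sqrt(s2), 0.02)
    done <- max(abs(mu_new - mu), abs(sigma_new - sigma)) < tol
    mu <- mu_new; sigma <- sigma_new
    if (done) break
  }
  sdist <- sapply(1:3, function(k)
    qnorm(c(0.25, 0.5, 0.75), mu[k], sigma[k]))
  sdist <- transform_cols(sdist)
  dimnames(sdist) <- list(pct_names, par_names)
  # MAP yields no posterior spread for the group mean: only the median row
  # of the Table-style group percentiles is defined
  gp <- sdist
  gp["p25", ] <- gp["p75", ] <- NA
  gp["p50", ] <- theta_to_num(mu)
  structure(list(
    subject_params = setNames(lapply(seq_len(J), function(j)
      theta_to_params(th[j, ])), enc$sites),
    group_percentiles = gp, subject_dist_percentiles = sdist,
    group_mu = mu, group_sigma = sigma,
    rhat = NULL, loglik = total_loglik(enc, th), samples = NULL,
    method = "hierarchical_map"), class = "fit_result")
}

theta_to_num <- function(th) c(plogis(th[1]), exp(th[2]), th[3])

cohort_nll <- function(th, enc) {
  sum(.nll_qlearn_multi_cpp(plogis(th[, 1]), exp(th[, 2]), th[, 3],
                            enc$choice, enc$reward, enc$reset,
                            enc$start, enc$len))
}

fit_mcmc <- function(enc, config, sweeps = 5L) {
  J <- length(enc$sites)
  n_keep <- config$n_iter - config$n_warmup
  th_init <- mle_by_subject(enc, prior_mu = c(0, 0, 0),
                            prior_sd = c(2, 2, 2))
  n_par <- 3L * J + 6L
  draws <- array(NA_real_, c(n_keep, config$n_chains, n_par))
  for (chain in seq_len(config$n_chains)) {
    set.seed((config$rng_seed * 101L + chain * 7919L) %% .Machine$integer.max)
    th <- th_init + matrix(rnorm(J * 3, 0, 0.3), J, 3)
    mu <- colMeans(th)
    sigma <- pmax(apply(th, 2, sd), 0.2)
    # warmup phase 1: component-wise slice; phase 2 onwards: slice along
    # per-subject eigen-directions of the warmup posterior covariance,
    # which decorrelates the alpha-beta likelihood trade-off
    rot <- rep(as.numeric(diag(3)), J)
    wids <- matrix(1, J, 3)
    n_ad <- max(20L, config$n_warmup %/% 2L)
    ad_draws <- array(NA_real_, c(config$n_warmup, J, 3))
    adapt_from <- function(it_lo, it_hi) {
      for (j in seq_len(J)) {
        cv <- stats::cov(ad_draws[it_lo:it_hi, j, ])
        eg <- tryCatch(eigen(cv, symmetric = TRUE),
                       error = function(e) NULL)
        if (!is.null(eg) && all(eg$values > 1e-10)) {
          rot[(9 * (j - 1) + 1):(9 * j)] <<- as.numeric(eg$vectors)
          wids[j, ] <<- pmax(2.5 * sqrt(eg$values), 0.02)
        }
      }
    }
    for (it in seq_len(config$n_iter)) {
      for (sw in seq_len(sweeps)) {
        th <- .slice_scan_cpp(th, mu, sigma, enc$choice, enc$reward,
                              enc$reset, enc$start, enc$len, rot, wids, 50L)
        for (k in 1:3) {
          # conjugate Gibbs for the group mean (centered parameterization)
          prec <- J / sigma[k]^2 + 1 / config$prior_mean_sd^2
          m <- sum(th[, k]) / sigma[k]^2 / prec
          mu[k] <- rnorm(1, m, sqrt(1 / prec))
          # slice for the group SD on the log scale (half-Normal prior)
          logf <- function(ls) {
            s <- exp(ls)
            sum(dnorm(th[, k], mu[k], s, log = TRUE)) +
              dnorm(s, 0, config$prior_sigma_sd, log = TRUE) + ls
          }
          sigma[k] <- exp(slice1(log(sigma[k]), logf))
        }
      # interleaved non-centered (ASIS) slice moves: with the standardized
      # subject effects held fixed, translate / rescale the whole column,
      # which breaks the group-mean and group-scale funnels
      for (k in 1:3) {
        th_k <- th[, k]
        # translation: mu' = mu + e, theta' = theta + e
        logf_t <- function(e) {
          th_p <- th; th_p[, k] <- th_k + e
          -cohort_nll(th_p, enc) +
            dnorm(mu[k] + e, 0, config$prior_mean_sd, log = TRUE)
        }
        e <- slice1(0, logf_t, w = max(0.05, sigma[k] / sqrt(J)))
        mu[k] <- mu[k] + e
        th[, k] <- th_k + e
        # rescale: sigma' = exp(lc) sigma, theta' = mu + exp(lc)(theta - mu)
        th_k <- th[, k]
        logf_s <- function(lc) {
          cc <- exp(lc)
          th_p <- th; th_p[, k] <- mu[k] + cc * (th_k - mu[k])
          -cohort_nll(th_p, enc) +
            dnorm(cc * sigma[k], 0, config$prior_sigma_sd, log = TRUE) + lc
        }
        lc <- slice1(0, logf_s, w = 0.3)
        sigma[k] <- exp(lc) * sigma[k]
        th[, k] <- mu[k] + exp(lc) * (th_k - mu[k])
      }
      }
      if (it <= config$n_warmup) {
        ad_draws[it, , ] <- th
        # two-stage warmup adaptation: crude directions at mid-warmup, then
        # refined ones (from the better-mixed second half) at warmup end
        if (it == n_ad) adapt_from(1L, n_ad)
        if (it == config$n_warmup) adapt_from(n_ad + 1L, config$n_warmup)
      }
      if (it > config$n_warmup)
        draws[it - config$n_warmup, chain, ] <- c(as.numeric(th), mu, sigma)
    }
  }
  pn <- c(paste0("theta[", rep(seq_len(J), 3), ",",
                 rep(1:3, each = J), "]"),
          paste0("mu[", 1:3, "]"), paste0("sigma[", 1:3, "]"))
  rh <- setNames(vapply(seq_len(n_par), function(p)
    rhat(draws[, , p]), numeric(1)), pn)

  # posterior medians per subject, natural scale
  med_th <- matrix(0, J, 3)
  for (j in seq_len(J))
    for (k in 1:3)
      med_th[j, k] <- median(draws[, , (k - 1L) * J + j])
  # group percentiles of the transformed group-mean parameters
  mu_draws <- matrix(draws[, , (3L * J + 1L):(3L * J + 3L)], ncol = 3)
  sg_draws <- matrix(draws[, , (3L * J + 4L):(3L * J + 6L)], ncol = 3)
  gp <- apply(transform_cols(mu_draws), 2, quantile,
              probs = c(0.25, 0.5, 0.75))
  dimnames(gp) <- list(pct_names, par_names)
  # percentiles of the implied subject-level distribution (posterior mean)
  sdist <- sapply(1:3, function(k)
    sapply(c(0.25, 0.5, 0.75), function(p)
      mean(qnorm(p, mu_draws[, k], sg_draws[, k]))))
  sdist <- transform_cols(sdist)
  dimnames(sdist) <- list(pct_names, par_names)

  if (any(rh > 1.1, na.rm = TRUE))
    warning("Rhat > 1.1 for some parameters; chains may not have converged",
            call. = FALSE)
  structure(list(
    subject_params = setNames(lapply(seq_len(J), function(j)
      theta_to_params(med_th[j, ])), enc$sites),
    group_percentiles = gp, subject_dist_percentiles = sdist,
    rhat = rh, loglik = total_loglik(enc, med_th),
    samples = draws, method = "hierarchical_mcmc"), class = "fit_result")
}

#' Per-trial Q-value trajectories in both reference frames
#'
#' Forward-simulates the Q recursion with each subject's fitted parameters
#' on the observed choices and rewards, and reports decision-time values:
#' `q_contra`, `q_ipsi`, `dq_chosen = Q(chosen) - Q(unchosen)`,
#' `dq_contra = Q(contra) - Q(ipsi)`, plus per-site standardised versions
#' (`dq_chosen_std`, `dq_contra_std`). Rows align one-to-one with `trials`;
#' abandoned trials carry the prevailing Q values and `NA` for the
#' chosen-frame difference.
#'
#' @param subject_params named list of [agent_params()] keyed by site_id
#'   (e.g. `fit_result$subject_params`).
#' @param trials multi-subject trial table.
#' @param q_reset_per_session see [negloglik()].
#' @return data.frame aligned with `trials`.
#' @export
compute_q_trajectories <- function(subject_params, trials,
                                   q_reset_per_session = FALSE) {
  n <- nrow(trials)
  qc <- numeric(n); qi <- numeric(n)
  for (site in unique(trials$site_id)) {
    if (!site %in% names(subject_params))
      stop("no fitted parameters for site ", site, call. = FALSE)
    sel <- which(trials$site_id == site)
    tr <- trials[sel, ]
    comp <- tr$abandoned == 0L & !is.na(tr$choice)
    enc <- encode_trials(tr, q_reset_per_session)
    alpha <- subject_params[[site]]$alpha
    qp <- .qpath_cpp(alpha, enc$choice, enc$reward, enc$reset)
    # states S_0..S_m: decision-time Q of completed trial k is S_{k-1}
    last_c <- enc$choice[length(enc$choice)]
    last_r <- enc$reward[length(enc$reward)]
    S_qc <- c(qp[, 1], if (last_c == 1L)
      q_update(qp[nrow(qp), 1], last_r, alpha) else qp[nrow(qp), 1])
    S_qi <- c(qp[, 2], if (last_c == 0L)
      q_update(qp[nrow(qp), 2], last_r, alpha) else qp[nrow(qp), 2])
    pos_prev <- cumsum(comp) - comp  # completed trials before each row
    qc[sel] <- S_qc[pos_prev + 1L]
    qi[sel] <- S_qi[pos_prev + 1L]
  }
  dq_contra <- qc - qi
  dq_chosen <- ifelse(trials$choice == "contra", dq_contra, -dq_contra)
  out <- data.frame(site_id = trials$site_id, q_contra = qc, q_ipsi = qi,
                    dq_chosen = dq_chosen, dq_contra = dq_contra,
                    dq_chosen_std = NA_real_, dq_contra_std = NA_real_)
  for (site in unique(out$site_id)) {
    sel <- out$site_id == site
    for (col in c("dq_chosen", "dq_contra")) {
      x <- out[[col]][sel]
      s <- sd(x, na.rm = TRUE)
      out[[paste0(col, "_std")]][sel] <-
        if (is.finite(s) && s > 0) (x - mean(x, na.rm = TRUE)) / s else 0
    }
  }
  out
}
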