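test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
  set.seed(171)
  for (i in 1:1000) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

make_synth_epochs <- function(n_sites = 6, n_per_site = 150, noise = 0.5,
                              b_choice = 0.5, b_value = 0.3, b_int = 0,
                              b0 = 0.1, site_sd = 0.2, seed = 181) {
  set.seed(seed)
  site <- factor(rep(sprintf("s%02d", seq_len(n_sites)), each = n_per_site))
  n <- length(site)
  choice <- rbinom(n, 1, 0.5)
  value <- rnorm(n)
  site_fx <- rnorm(n_sites, 0, site_sd)[as.integer(site)]
  mu <- b0 + b_choice * choice + b_value * value +
    b_int * choice * value + site_fx
  vals <- sapply(1:45, function(t) mu + rnorm(n, 0, noise))
  epochs <- structure(list(values = vals, time_axis = (-15:29) / 15,
                           alignment_event = "lever_present",
                           trial_index_map = seq_len(n),
                           dropped = integer(0)), class = "epoch_matrix")
  design <- data.frame(choice = choice, value = value, site = site)
  attr(design, "frame") <- "chosen"
  list(epochs = epochs, design = design)
}

test_that("pointwise mixed regression recovers generating coefficients", {
  d <- make_synth_epochs()
  res <- pointwise_mixed_regression(d$epochs, d$design)
  expect_s3_class(res, "regression_result")
  expect_equal(sort(unique(res$term)),
               sort(c("(Intercept)", "choice", "value", "choice:value")))
  for (term in c("choice", "value", "choice:value")) {
    sub <- res[res$term == term, ]
    expect_equal(nrow(sub), 45)
    truth <- c(choice = 0.5, value = 0.3, `choice:value` = 0)[term]
    # 3-SE coverage across the 45 independent timepoints, plus an
    # unbiasedness check on the average
    expect_gte(mean(abs(sub$estimate - truth) <= 3 * sub$se), 0.95)
    expect_lt(abs(mean(sub$estimate) - truth),
              4 * mean(sub$se) / sqrt(45) + 1e-8)
  }
  # adjusted p never smaller than raw p; tiers consistent
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all((res$tier != "ns") == (res$p_adj < 0.05)))
  # strong true effects are detected
  expect_gte(mean(res$p_adj[res$term == "choice"] < 0.001), 44 / 45)
})

test_that("the closed-form REML engine agrees with lme4 on the
           random-intercept model", {
  d <- make_synth_epochs(n_sites = 5, n_per_site = 300)
  # lme4 path (satterthwaite forces it) vs profiled closed form
  r1 <- pointwise_mixed_regression(d$epochs, d$design,
                                   random = "intercept",
                                   df_method = "satterthwaite")
  r2 <- pointwise_mixed_regression(d$epochs, d$design,
                                   random = "intercept",
                                   df_method = "wald")
  ord <- order(r1$term, r1$time_s)
  expect_equal(r1$estimate[ord], r2$estimate[order(r2$term, r2$time_s)],
               tolerance = 1e-5)
  expect_equal(r1$se[ord], r2$se[order(r2$term, r2$time_s)],
               tolerance = 1e-4)
  # large-n: Satterthwaite t and Wald z agree closely away from p ~ 0
  mid <- r1$p[ord] > 1e-4
  expect_equal(r1$p[ord][mid], r2$p[order(r2$term, r2$time_s)][mid],
               tolerance = 0.05)
})

test_that("a permuted value regressor stays null after BH", {
  hits <- 0L
  for (r in 1:10) {
    d <- make_synth_epochs(b_value = 0.3, seed = 190 + r)
    d$design$value <- sample(d$design$value)  # break the association
    res <- pointwise_mixed_regression(d$epochs, d$design,
                                      df_method = "wald")
    if (any(res$p_adj[res$term == "value"] < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("single-site zero-noise data reduces to exact OLS", {
  set.seed(201)
  n <- 80
  design <- data.frame(choice = rbinom(n, 1, 0.5), value = rnorm(n),
                       site = factor(rep("s1", n)))
  attr(design, "frame") <- "chosen"
  y <- 0.2 + 0.7 * design$choice - 0.4 * design$value +
    0.1 * design$choice * design$value
  epochs <- structure(list(values = matrix(rep(y, 45), ncol = 45),
                           time_axis = (-15:29) / 15,
                           alignment_event = "lever_present",
                           trial_index_map = seq_len(n),
                           dropped = integer(0)), class = "epoch_matrix")
  res <- pointwise_mixed_regression(epochs, design)
  est <- res$estimate[res$time_s == 0]
  names(est) <- res$term[res$time_s == 0]
  expect_equal(unname(est[c("(Intercept)", "choice", "value",
                            "choice:value")]),
               c(0.2, 0.7, -0.4, 0.1), tolerance = 1e-8)
})

test_that("cluster-robust covariance matches the sandwich formula", {
  set.seed(211)
  n <- 400; k <- 3
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
  cl <- rep(1:8, each = n / 8)
  e <- rnorm(n)
  V <- cluster_robust_cov(X, e, cl)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
  expect_equal(V, unname(sandwich_oracle(X, e, cl)), tolerance = 1e-10)
  # cross-check against the sandwich package on a fitted model
  skip_if_not_installed("sandwich")
  df <- data.frame(y = X %*% c(1, 0.5, -0.3) + e, x1 = X[, 2], x2 = X[, 3],
                   cl = cl)
  m <- lm(y ~ x1 + x2, data = df)
  V2 <- cluster_robust_cov(X, resid(m), cl)
  Vref <- sandwich::vcovCL(m, cluster = df$cl, type = "HC1",
                           cadjust = TRUE)
  expect_equal(unname(V2), unname(Vref), tolerance = 1e-6)
  expect_error(cluster_robust_cov(X, e, rep(1, n)), "2 clusters")
})

test_that("robust and classical SEs agree under independence and diverge
           under within-cluster correlation", {
  set.seed(221)
  n <- 800
  X <- cbind(1, rnorm(n))
  # one cluster per observation: CR0 equals HC0, close to classical
  e <- rnorm(n)
  V_cr <- cluster_robust_cov(X, e, seq_len(n), type = "CR0")
  V_cl <- solve(crossprod(X)) * sum(e^2) / (n - 2)
  expect_equal(sqrt(diag(V_cr)), sqrt(diag(V_cl)), tolerance = 0.1)
  # perfectly correlated residuals within clusters inflate the robust SE
  cl <- rep(1:10, each = n / 10)
  e2 <- rnorm(10)[cl]
  V_cr2 <- cluster_robust_cov(X, e2, cl)
  V_cl2 <- solve(crossprod(X)) * sum(e2^2) / (n - 2)
  expect_gt(sqrt(V_cr2[1, 1]), sqrt(V_cl2[1, 1]))
})

test_that("kernel regression exactly recovers noise-free constructions", {
  set.seed(231)
  fs <- 15
  # generator kernel confined to the modeled 0..29 lag window so the trace
  # is exactly representable by the design
  kern <- calcium_kernel(photometry_config())[1:30]
  # two synthetic sites; jittered inter-event delays keep the lagged
  # indicator columns of the three events linearly independent
  gen_site <- function(site_seed) {
    set.seed(site_seed)
    n_tr <- 40
    t_nose <- seq(2, by = 10, length.out = n_tr)
    t_present <- t_nose + sample(seq(0.1, 1, 0.1), n_tr, TRUE)
    t_press <- t_present + sample(seq(0.3, 2, 0.1), n_tr, TRUE)
    trials <- data.frame(
      site_id = paste0("s", site_seed), session_id = 1L,
      trial_index = seq_len(n_tr), block_id = 1L, high_side = "contra",
      choice = rep(c("contra", "ipsi"), length.out = n_tr),
      reward = 1L,
      prev_choice = rep(c("contra", "ipsi"), length.out = n_tr),
      prev_reward = rep(c(1L, 0L), each = 2, length.out = n_tr),
      t_nose_poke = t_nose, t_lever_present = t_present,
      t_lever_press = t_press, t_outcome = t_press + 0.4,
      press_latency = t_press - t_present, abandoned = 0L)
    n <- ceiling((max(t_press) + 5) * fs)
    z <- numeric(n)
    amp <- ifelse(trials$choice == "contra", 1, 0.4) +
      0.5 * trials$prev_reward
    for (i in seq_len(n_tr)) {
      k0 <- round(trials$t_lever_present[i] * fs) + 1
      idx <- k0:(k0 + length(kern) - 1)
      z[idx] <- z[idx] + amp[i] * kern
    }
    list(z = z, trials = trials, session_offsets = 1L, session_ids = 1L)
  }
  sites <- list(gen_site(1), gen_site(2))
  fit <- kernel_regression(sites)
  kl <- fit$kernels
  # lever-present kernel for each condition reproduces the generator;
  # nose-poke and press kernels absorb nothing systematic
  for (ch in c("contra", "ipsi")) {
    for (pr in c(1L, 0L)) {
      est <- kl$estimate[kl$event == "lever_present" & kl$choice == ch &
                           kl$prev_reward == pr]
      truth <- numeric(45)
      a <- ifelse(ch == "contra", 1, 0.4) + 0.5 * pr
      truth[16:45] <- a * kern
      expect_equal(est, truth, tolerance = 1e-6)
    }
  }
  # all-zero trace gives all-zero coefficients
  sites0 <- lapply(sites, function(s) { s$z <- numeric(length(s$z)); s })
  fit0 <- kernel_regression(sites0)
  expect_equal(max(abs(fit0$coef)), 0, tolerance = 1e-10)
})
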