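#' Cluster-robust (sandwich) covariance of least-squares coefficients
#'
#' CR1-scaled sandwich estimator,
#' `V = c (X'X)^{-1} (sum_g X_g' e_g e_g' X_g) (X'X)^{-1}` with
#' `c = G/(G-1) * (n-1)/(n-k)`, tolerating arbitrarily correlated residuals
#' within clusters (here: recording sites / animals). `type = "CR0"` drops
#' the small-sample factor.
#'
#' @param X design matrix (dense or `Matrix` sparse).
#' @param residuals residual vector.
#' @param clusters cluster id per row.
#' @param type `"CR1"` (default) or `"CR0"`.
#' @return symmetric PSD covariance matrix of the coefficients.
#' @export
cluster_robust_cov <- function(X, residuals, clusters, type = c("CR1",
                                                                "CR0")) {
  type <- match.arg(type)
  clusters <- as.factor(clusters)
  G <- nlevels(clusters)
  if (G < 2) stop("need >= 2 clusters", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  XtX <- as.matrix(Matrix::crossprod(X))
  bread <- solve(XtX)
  p <- ncol(X)
  meat <- matrix(0, p, p)
  for (g in levels(clusters)) {
    sel <- clusters == g
    u <- as.numeric(Matrix::crossprod(X[sel, , drop = FALSE],
                                      residuals[sel]))
    meat <- meat + tcrossprod(u)
  }
  c_adj <- if (type == "CR1") G / (G - 1) * (n - 1) / (n - k) else 1
  V <- c_adj * bread %*% meat %*% bread
  (V + t(V)) / 2
}

# sparse lagged-indicator design for one site's concatenated z series
kernel_design_site <- function(z, trials, session_offsets, session_ids,
                               fs, lags, events, conditions) {
  n <- length(z)
  off <- setNames(session_offsets, session_ids)
  lag_idx <- lags[1]:lags[2]
  nlag <- length(lag_idx)
  ncond <- nrow(conditions)
  eligible <- trials$abandoned == 0L & !is.na(trials$choice) &
    trials$prev_choice != "none" & !is.na(trials$prev_reward)
  cond_of <- rep(NA_integer_, nrow(trials))
  for (ci in seq_len(ncond)) {
    m <- eligible & trials$choice == conditions$choice[ci] &
      trials$prev_reward == conditions$prev_reward[ci]
    cond_of[m] <- ci
  }
  acc_i <- list(); acc_j <- list()
  for (ei in seq_along(events)) {
    tcol <- trials[[events[ei]]]
    centers <- round((off[as.character(trials$session_id)] - 1L) +
                     tcol * fs) + 1L
    use <- which(!is.na(cond_of) & !is.na(centers))
    if (length(use) == 0) next
    # vectorised over trials: rows are centers x lags
    rows <- rep(centers[use], each = nlag) + rep(lag_idx, length(use))
    col0 <- ((ei - 1L) * ncond + (cond_of[use] - 1L)) * nlag
    cols <- rep(col0, each = nlag) + rep(seq_len(nlag), length(use))
    ok <- rows >= 1L & rows <= n
    acc_i[[ei]] <- rows[ok]
    acc_j[[ei]] <- cols[ok]
  }
  list(i = unlist(acc_i), j = unlist(acc_j), n = n)
}

#' Multi-event kernel regression of the continuous signal
#'
#' Models the z-scored trace as a sum of event-locked kernels: for each of
#' three events (nose poke, lever presentation, lever press) and each of
#' four conditions (contralateral / ipsilateral choice x previous trial
#' rewarded / unrewarded), a set of lagged indicator regressors spanning
#' 1 s before to 2 s after the event (45 lags at 15 Hz), plus a global
#' intercept. Solved by least squares over the concatenated records of all
#' sites; standard errors use the cluster-robust sandwich estimator grouped
#' by site (classical OLS standard errors when only one site is supplied).
#'
#' @param site_data list with one element per site, each a list with `z`
#'   (preprocessed series), `trials`, `session_offsets`, `session_ids`.
#' @param fs sampling rate (Hz).
#' @param lags two-element integer vector of lag range in samples
#'   (default `c(-15, 29)`).
#' @param events trial-table timestamp columns to model.
#' @return a `kernel_fit` list: `kernels` (data.frame: event, choice,
#'   prev_reward, lag_s, estimate, se), `intercept`, `coef`, `vcov`,
#'   `lags`, `n_obs`.
#' @export
kernel_regression <- function(site_data, fs = 15, lags = c(-15L, 29L),
                              events = c("t_nose_poke", "t_lever_present",
                                         "t_lever_press")) {
  conditions <- expand.grid(choice = c("contra", "ipsi"),
                            prev_reward = c(1L, 0L),
                            stringsAsFactors = FALSE)
  lag_idx <- lags[1]:lags[2]
  nlag <- length(lag_idx)
  ncond <- nrow(conditions)
  p <- length(events) * ncond * nlag

  ylist <- lapply(site_data, `[[`, "z")
  row_off <- cumsum(c(0L, vapply(ylist, length, integer(1))))
  ii <- integer(0); jj <- integer(0); cl <- integer(0)
  for (s in seq_along(site_data)) {
    sd_ <- site_data[[s]]
    d <- kernel_design_site(sd_$z, sd_$trials, sd_$session_offsets,
                            sd_$session_ids, fs, lags, events, conditions)
    ii <- c(ii, d$i + row_off[s])
    jj <- c(jj, d$j)
  }
  y <- unlist(ylist, use.names = FALSE)
  n <- length(y)
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, p))
  X <- cbind(X, Matrix::Matrix(1, n, 1, sparse = TRUE))
  XtX <- Matrix::crossprod(X)
  ch <- tryCatch(Matrix::Cholesky(XtX), error = function(e) NULL)
  if (is.null(ch)) {
    colsum <- Matrix::colSums(X)
    stop("rank-deficient kernel design; empty or collinear columns: ",
         paste(which(colsum == 0), collapse = ","), call. = FALSE)
  }
  beta <- as.numeric(Matrix::solve(ch, Matrix::crossprod(X, y)))
  r <- y - as.numeric(X %*% beta)
  clusters <- rep(seq_along(site_data),
                  vapply(ylist, length, integer(1)))
  V <- if (length(site_data) >= 2) {
    cluster_robust_cov(X, r, clusters)
  } else {
    s2 <- sum(r^2) / (n - ncol(X))
    s2 * as.matrix(Matrix::solve(XtX))
  }
  se <- sqrt(pmax(diag(V), 0))

  grid <- expand.grid(lag = lag_idx, cond = seq_len(ncond),
                      event = seq_along(events))
  kernels <- data.frame(
    event = sub("^t_", "", events[grid$event]),
    choice = conditions$choice[grid$cond],
    prev_reward = conditions$prev_reward[grid$cond],
    lag_s = grid$lag / fs,
    estimate = beta[seq_len(p)],
    se = se[seq_len(p)],
    stringsAsFactors = FALSE)
  structure(list(kernels = kernels, intercept = beta[p + 1L],
                 coef = beta, vcov = V, lags = lags, n_obs = n),
            class = "kernel_fit")
}
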