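#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, applied per regressor across the
#' ensemble of epoch timepoints.
#'
#' @param pvals p-values in \[0,1\].
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must be in [0,1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

significance_tier <- function(p_adj) {
  cut(p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("0.001", "0.01", "0.05", "ns"))
}

#' Build the trial-level design for the pointwise regression
#'
#' @param trials trial table.
#' @param qtraj aligned Q-trajectory table from [compute_q_trajectories()].
#' @param frame `"chosen"` (Q chosen - unchosen) or `"contra"`
#'   (Q contra - ipsi); the standardised column of that frame becomes the
#'   value regressor.
#' @param include_log_latency add log lever-press latency as a covariate.
#' @return data.frame with `choice` (contra = 1), `value`, `site`, and
#'   optionally `log_latency`; rows align with `trials`.
#' @export
build_pointwise_design <- function(trials, qtraj,
                                   frame = c("chosen", "contra"),
                                   include_log_latency = FALSE) {
  frame <- match.arg(frame)
  value <- if (frame == "chosen") qtraj$dq_chosen_std else qtraj$dq_contra_std
  d <- data.frame(choice = as.numeric(trials$choice == "contra"),
                  value = value,
                  site = factor(trials$site_id))
  if (include_log_latency) d$log_latency <- log(trials$press_latency)
  attr(d, "frame") <- frame
  d
}

fixef_table_wald <- function(m) {
  co <- summary(m)$coefficients
  data.frame(term = rownames(co), estimate = co[, "Estimate"],
             se = co[, "Std. Error"],
             p = 2 * pnorm(-abs(co[, "t value"])),
             row.names = NULL, stringsAsFactors = FALSE)
}

fixef_table_satt <- function(m) {
  mt <- suppressWarnings(suppressMessages(lmerTest::as_lmerModLmerTest(m)))
  co <- suppressWarnings(summary(mt))$coefficients
  data.frame(term = rownames(co), estimate = co[, "Estimate"],
             se = co[, "Std. Error"], p = co[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

fixef_table_lm <- function(m) {
  # summary.lm warns on numerically perfect fits; estimates remain valid
  co <- suppressWarnings(summary(m))$coefficients
  data.frame(term = rownames(co), estimate = co[, "Estimate"],
             se = co[, "Std. Error"], p = co[, "Pr(>|t|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Exact REML fit of the random-intercept model y = Xb + u[site] + e via the
# profiled variance ratio lambda = sigma_u^2/sigma_e^2. Block-diagonal
# Woodbury identities reduce each lambda evaluation to O(sites * p^2), and
# the per-site X summaries are shared across the 45 timepoints. Matches
# lme4::lmer(y ~ X + (1|site), REML = TRUE) up to optimizer tolerance.
ri_reml_prepare <- function(X, site) {
  site <- as.factor(site)
  idx <- split(seq_len(nrow(X)), site)
  list(idx = idx,
       A = lapply(idx, function(i) crossprod(X[i, , drop = FALSE])),
       a = lapply(idx, function(i) colSums(X[i, , drop = FALSE])),
       n_i = vapply(idx, length, numeric(1)),
       X = X, n = nrow(X), p = ncol(X))
}

ri_reml_fit <- function(prep, y) {
  S <- length(prep$idx)
  Xy_i <- lapply(prep$idx, function(i)
    crossprod(prep$X[i, , drop = FALSE], y[i]))
  s_i <- vapply(prep$idx, function(i) sum(y[i]), numeric(1))
  yy_i <- vapply(prep$idx, function(i) sum(y[i]^2), numeric(1))
  n <- prep$n; p <- prep$p
  solve_at <- function(lam) {
    c_i <- lam / (1 + lam * prep$n_i)
    XtVX <- Reduce(`+`, lapply(seq_len(S), function(i)
      prep$A[[i]] - c_i[i] * tcrossprod(prep$a[[i]])))
    XtVy <- Reduce(`+`, lapply(seq_len(S), function(i)
      Xy_i[[i]] - c_i[i] * prep$a[[i]] * s_i[i]))
    yVy <- sum(yy_i - c_i * s_i^2)
    b <- solve(XtVX, XtVy)
    rss <- yVy - sum(b * XtVy)
    list(b = b, XtVX = XtVX, rss = rss,
         ldetV = sum(log1p(lam * prep$n_i)))
  }
  negREML <- function(loglam) {
    f <- solve_at(exp(loglam))
    s2 <- f$rss / (n - p)
    0.5 * ((n - p) * log(s2) + f$ldetV +
             determinant(f$XtVX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(negREML, c(-12, 8))
  lam <- exp(opt$minimum)
  # compare against the boundary lambda -> 0 (plain OLS)
  if (negREML(-30) < opt$objective) lam <- exp(-30)
  f <- solve_at(lam)
  s2 <- f$rss / (n - p)
  se <- sqrt(pmax(diag(solve(f$XtVX)) * s2, 0))
  tv <- as.numeric(f$b) / se
  data.frame(term = colnames(prep$X), estimate = as.numeric(f$b), se = se,
             p = 2 * pnorm(-abs(tv)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-timepoint mixed-effects regression of event-locked signal
#'
#' At each of the epoch's 45 timepoints, fits a linear mixed model of the
#' z-scored signal on choice (contra = 1), the standardised value difference
#' in the declared frame, their interaction, an intercept, and optionally
#' log press latency, with random effects by recording site. The default
#' random-effects structure is intercept plus choice and value slopes,
#' falling back to random intercepts only (and recording a note) when that
#' fit fails; with a single site the model degenerates to OLS. P-values use
#' Satterthwaite degrees of freedom by default (`df_method = "wald"` gives
#' the large-sample normal approximation, indistinguishable at thousands of
#' trials and used on the hot path of replicated simulations). P-values are
#' then BH-adjusted per regressor across timepoints.
#'
#' @param epochs an `epoch_matrix` from [extract_epochs()].
#' @param design data.frame from [build_pointwise_design()], one row per
#'   *kept* epoch trial (subset rows by `epochs$trial_index_map` before
#'   calling if you built the design for all trials).
#' @param random `"slopes"` or `"intercept"`.
#' @param df_method `"satterthwaite"` or `"wald"`.
#' @param engine `"auto"` picks the closed-form profiled-REML solver for
#'   the random-intercept/Wald combination (identical estimator, much
#'   faster across 45 timepoints) and lme4 otherwise; `"lme4"` forces the
#'   general path.
#' @return a `regression_result` data.frame with columns `term`, `time_s`,
#'   `estimate`, `se`, `p`, `p_adj`, `tier`; attributes `frame`,
#'   `alignment_event`, `n_sites`, `n_trials`, `notes`.
#' @export
pointwise_mixed_regression <- function(epochs, design,
                                       random = c("slopes", "intercept"),
                                       df_method = c("satterthwaite",
                                                     "wald"),
                                       engine = c("auto", "lme4")) {
  random <- match.arg(random)
  df_method <- match.arg(df_method)
  engine <- match.arg(engine)
  if (nrow(design) != nrow(epochs$values))
    stop("design rows must align with epoch trials", call. = FALSE)
  keep <- stats::complete.cases(design)
  design <- design[keep, , drop = FALSE]
  values <- epochs$values[keep, , drop = FALSE]
  n_sites <- length(unique(design$site))
  has_lat <- "log_latency" %in% names(design)
  fe <- if (has_lat) "choice * value + log_latency" else "choice * value"
  notes <- character(0)

  if (engine == "auto" && random == "intercept" && df_method == "wald" &&
      n_sites >= 2) {
    Xmm <- cbind(`(Intercept)` = 1, choice = design$choice,
                 value = design$value)
    if (has_lat) Xmm <- cbind(Xmm, log_latency = design$log_latency)
    Xmm <- cbind(Xmm, `choice:value` = design$choice * design$value)
    prep <- ri_reml_prepare(Xmm, design$site)
    res <- vector("list", ncol(values))
    for (t in seq_len(ncol(values))) {
      tab <- tryCatch(ri_reml_fit(prep, values[, t]),
                      error = function(e) NULL)
      if (is.null(tab)) {
        notes <- c(notes, sprintf("timepoint %d: fit failed", t))
        next
      }
      tab$time_s <- epochs$time_axis[t]
      res[[t]] <- tab
    }
    out <- do.call(rbind, res)
    return(finish_regression(out, design, epochs, n_sites, notes))
  }

  single_site <- n_sites < 2
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  make_fit <- function(rterm, y) {
    dd <- design; dd$y <- y
    f <- stats::as.formula(paste("y ~", fe, "+", rterm))
    lmerTest::lmer(f, data = dd, REML = TRUE, control = ctrl)
  }
  rterm_full <- "(1 + choice + value | site)"
  rterm_int <- "(1 | site)"

  base_fit <- NULL
  rterm <- if (random == "slopes") rterm_full else rterm_int
  if (!single_site) {
    base_fit <- tryCatch(
      suppressWarnings(suppressMessages(make_fit(rterm, values[, 1]))),
      error = function(e) NULL)
    if (is.null(base_fit) && rterm != rterm_int) {
      notes <- c(notes, "random slopes failed; random intercepts only")
      rterm <- rterm_int
      base_fit <- tryCatch(
        suppressWarnings(suppressMessages(make_fit(rterm, values[, 1]))),
        error = function(e) NULL)
    }
    if (is.null(base_fit)) single_site <- TRUE  # last-resort OLS
  }

  res <- vector("list", ncol(values))
  for (t in seq_len(ncol(values))) {
    y <- values[, t]
    tab <- tryCatch({
      if (single_site) {
        dd <- design; dd$y <- y
        fixef_table_lm(lm(stats::as.formula(paste("y ~", fe)), data = dd))
      } else {
        m <- suppressWarnings(suppressMessages(
          if (t == 1) base_fit else lme4::refit(base_fit, y)))
        if (df_method == "satterthwaite") fixef_table_satt(m)
        else fixef_table_wald(m)
      }
    }, error = function(e) NULL)
    if (is.null(tab)) {
      notes <- c(notes, sprintf("timepoint %d: fit failed", t))
      next
    }
    tab$time_s <- epochs$time_axis[t]
    res[[t]] <- tab
  }
  out <- do.call(rbind, res)
  finish_regression(out, design, epochs, n_sites, notes)
}

finish_regression <- function(out, design, epochs, n_sites, notes) {
  out$p_adj <- NA_real_
  for (term in unique(out$term)) {
    sel <- out$term == term
    out$p_adj[sel] <- bh_adjust(out$p[sel])
  }
  out$tier <- significance_tier(out$p_adj)
  out <- out[, c("term", "time_s", "estimate", "se", "p", "p_adj", "tier")]
  attr(out, "frame") <- attr(design, "frame")
  attr(out, "alignment_event") <- epochs$alignment_event
  attr(out, "n_sites") <- n_sites
  attr(out, "n_trials") <- nrow(design)
  attr(out, "notes") <- notes
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Test for a sustained significant effect in a time window
#'
#' An effect counts as sustained when at least `min_run` consecutive
#' timepoints inside `window_s` are BH-significant at `alpha`.
#'
#' @param result a `regression_result`.
#' @param term regressor name (e.g. `"choice:value"`).
#' @param window_s two-element window in seconds relative to the event.
#' @param alpha significance level on adjusted p-values.
#' @param min_run consecutive significant samples required.
#' @return logical.
#' @export
sustained_significance <- function(result, term, window_s = c(0.25, 1.0),
                                   alpha = 0.05, min_run = 4L) {
  sel <- result$term == term & result$time_s >= window_s[1] &
    result$time_s <= window_s[2]
  sig <- result$p_adj[sel][order(result$time_s[sel])] < alpha
  if (length(sig) == 0) return(FALSE)
  r <- rle(sig)
  any(r$values & r$lengths >= min_run)
}
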