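#' Synthesize and preprocess photometry for every site of a cohort
#'
#' For each recording site: generate the raw trace under the configured
#' hypothesis, then run the preprocessing chain (high-pass FIR, dF/F,
#' z-score).
#'
#' @param trials cohort trial table.
#' @param qtraj aligned Q trajectories ([compute_q_trajectories()]).
#' @param pconfig a [photometry_config()].
#' @param spec a [filter_spec()].
#' @return named list per site: `z`, `trials` (row indices into `trials`),
#'   `session_offsets`, `session_ids`, `trace`.
#' @export
prepare_cohort_signals <- function(trials, qtraj, pconfig,
                                   spec = filter_spec()) {
  b <- design_highpass_fir(spec)
  out <- list()
  for (site in unique(trials$site_id)) {
    sel <- which(trials$site_id == site)
    trace <- synthesize_trace(trials[sel, ], qtraj[sel, ], pconfig)
    pp <- preprocess_trace(trace, spec, b = b)
    out[[site]] <- list(z = pp$z, rows = sel,
                        session_offsets = trace$session_offsets,
                        session_ids = trace$session_ids, trace = trace)
  }
  out
}

#' Event-locked epochs across a cohort
#'
#' Extracts 45-sample epochs per site for the chosen alignment event and
#' stacks them, tracking which cohort trial each row came from.
#'
#' @param signals output of [prepare_cohort_signals()].
#' @param trials cohort trial table.
#' @param alignment `"nose_poke"`, `"lever_present"` or `"lever_press"`.
#' @param fs sampling rate (Hz).
#' @return an `epoch_matrix` whose `trial_index_map` indexes rows of
#'   `trials`.
#' @export
cohort_epochs <- function(signals, trials,
                          alignment = c("lever_present", "nose_poke",
                                        "lever_press"),
                          fs = 15) {
  alignment <- match.arg(alignment)
  tcol <- paste0("t_", alignment)
  vals <- list(); rows <- integer(0); dropped <- integer(0)
  time_axis <- NULL
  for (site in names(signals)) {
    sg <- signals[[site]]
    tr <- trials[sg$rows, ]
    off <- setNames(sg$session_offsets, sg$session_ids)
    tglob <- (off[as.character(tr$session_id)] - 1) / fs + tr[[tcol]]
    ep <- extract_epochs(sg$z, tglob, fs = fs,
                         session_offsets = sg$session_offsets,
                         alignment_event = alignment)
    vals[[site]] <- ep$values
    rows <- c(rows, sg$rows[ep$trial_index_map])
    dropped <- c(dropped, sg$rows[ep$dropped])
    time_axis <- ep$time_axis
  }
  structure(list(values = do.call(rbind, vals), time_axis = time_axis,
                 alignment_event = alignment, trial_index_map = rows,
                 dropped = dropped), class = "epoch_matrix")
}

site_condition_means <- function(values, site, cond) {
  agg <- list()
  for (s in unique(site)) {
    for (cn in unique(cond)) {
      sel <- site == s & cond == cn
      if (!any(sel)) next
      agg[[length(agg) + 1L]] <- list(site = s, cond = cn,
                                      mean = colMeans(values[sel, ,
                                                             drop = FALSE]),
                                      n = sum(sel))
    }
  }
  agg
}

condense_conditions <- function(agg, time_axis) {
  conds <- unique(vapply(agg, `[[`, character(1), "cond"))
  out <- list()
  for (cn in conds) {
    m <- do.call(rbind, lapply(Filter(function(a) a$cond == cn, agg),
                               `[[`, "mean"))
    n <- sum(vapply(Filter(function(a) a$cond == cn, agg), `[[`,
                    numeric(1), "n"))
    out[[cn]] <- data.frame(condition = cn, time_s = time_axis,
                            mean = colMeans(m),
                            se = apply(m, 2, sd) / sqrt(nrow(m)),
                            n_sites = nrow(m), n_trials = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Condition-averaged traces by previous-trial outcome
#'
#' Stay trials only (choice equal to the previous completed trial's choice),
#' split into contralateral / ipsilateral choice x previous trial rewarded /
#' unrewarded; mean epoch trace per condition with standard error across
#' sites.
#'
#' @param epochs `epoch_matrix` from [cohort_epochs()].
#' @param trials cohort trial table (indexed by `epochs$trial_index_map`).
#' @return a `binned_traces` data.frame (condition, time_s, mean, se,
#'   n_sites, n_trials); attribute `stay_only = TRUE`.
#' @export
bin_by_prev_outcome <- function(epochs, trials) {
  tr <- trials[epochs$trial_index_map, ]
  keep <- tr$abandoned == 0L & !is.na(tr$choice) &
    tr$prev_choice != "none" & tr$choice == tr$prev_choice &
    !is.na(tr$prev_reward)
  tr <- tr[keep, ]
  vals <- epochs$values[keep, , drop = FALSE]
  cond <- paste0(tr$choice, "_prev",
                 ifelse(tr$prev_reward == 1L, "Rew", "Unrew"))
  agg <- site_condition_means(vals, tr$site_id, cond)
  out <- condense_conditions(agg, epochs$time_axis)
  attr(out, "stay_only") <- TRUE
  class(out) <- c("binned_traces", "data.frame")
  out
}

#' Condition-averaged traces binned by the chosen-value difference
#'
#' All completed trials (stay and switch), split by choice and by bins of
#' the standardised Q(chosen) - Q(unchosen) difference; bin edges are
#' within-site quantiles.
#'
#' @param epochs `epoch_matrix`.
#' @param trials cohort trial table.
#' @param qtraj aligned Q trajectories.
#' @param n_bins number of value bins (>= 2).
#' @return a `binned_traces` data.frame.
#' @export
bin_by_dq <- function(epochs, trials, qtraj, n_bins = 3L) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  tr <- trials[epochs$trial_index_map, ]
  dq <- qtraj$dq_chosen_std[epochs$trial_index_map]
  keep <- tr$abandoned == 0L & !is.na(tr$choice) & !is.na(dq)
  tr <- tr[keep, ]; dq <- dq[keep]
  vals <- epochs$values[keep, , drop = FALSE]
  bin <- rep(NA_integer_, length(dq))
  for (s in unique(tr$site_id)) {
    sel <- tr$site_id == s
    edges <- quantile(dq[sel], probs = seq(0, 1, length.out = n_bins + 1L),
                      na.rm = TRUE)
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    bin[sel] <- as.integer(cut(dq[sel], edges, labels = FALSE,
                               include.lowest = TRUE))
  }
  cond <- paste0(tr$choice, "_dqbin", bin)
  agg <- site_condition_means(vals, tr$site_id, cond)
  out <- condense_conditions(agg, epochs$time_axis)
  attr(out, "stay_only") <- FALSE
  class(out) <- c("binned_traces", "data.frame")
  out
}

#' First sustained post-event zero crossing of a condition difference
#'
#' Computes the across-site mean difference trace between two groups of
#' epochs (by default contralateral minus ipsilateral choices) and returns
#' the time of the first post-event sign change that is sustained for at
#' least `min_run` samples, or `NA` when the selectivity never reverses.
#'
#' @param epochs `epoch_matrix` (typically aligned to the lever press).
#' @param trials cohort trial table.
#' @param contrast `"choice"` (contra - ipsi) or `"prev_reward"`
#'   (previously rewarded - unrewarded; the value-modulation contrast).
#' @param min_run samples the flipped sign must persist.
#' @param min_frac the flipped excursion must exceed this fraction of the
#'   peak absolute difference. A genuine side reversal flips by roughly the
#'   full selectivity magnitude, whereas the zero-phase high-pass filter's
#'   rebound around a decayed transient is bounded well below half the
#'   peak, so the default of 0.5 separates the two.
#' @return crossing time in seconds (`NA` if none).
#' @export
press_locked_crossing <- function(epochs, trials, contrast = c("choice",
                                                               "prev_reward"),
                                  min_run = 3L, min_frac = 0.5) {
  contrast <- match.arg(contrast)
  tr <- trials[epochs$trial_index_map, ]
  keep <- tr$abandoned == 0L & !is.na(tr$choice)
  if (contrast == "prev_reward")
    keep <- keep & !is.na(tr$prev_reward) & tr$prev_choice != "none"
  tr <- tr[keep, ]
  vals <- epochs$values[keep, , drop = FALSE]
  grp <- if (contrast == "choice") tr$choice == "contra"
         else tr$prev_reward == 1L
  # the value contrast is computed within each choice and then averaged, so
  # that differing choice composition across outcome groups cannot
  # masquerade as value-modulation dynamics
  strata <- if (contrast == "prev_reward") tr$choice
            else rep("all", nrow(tr))
  diffs <- list()
  for (s in unique(tr$site_id)) {
    for (st in unique(strata)) {
      sel <- tr$site_id == s & strata == st
      a <- vals[sel & grp, , drop = FALSE]
      b <- vals[sel & !grp, , drop = FALSE]
      if (nrow(a) == 0 || nrow(b) == 0) next
      diffs[[paste(s, st)]] <- colMeans(a) - colMeans(b)
    }
  }
  d <- colMeans(do.call(rbind, diffs))
  # early pre-event baseline correction: the zero-phase high-pass leaves a
  # shallow DC-like undershoot across the whole epoch that would otherwise
  # bias the sign logic
  base <- epochs$time_axis <= -0.7
  d <- d - mean(d[base])
  post <- which(epochs$time_axis >= 0)
  ref_sign <- sign(d[post[1]])
  if (ref_sign == 0) ref_sign <- sign(mean(d[epochs$time_axis < 0]))
  thresh <- min_frac * max(abs(d))
  flipped <- sign(d[post]) == -ref_sign & abs(d[post]) > thresh
  r <- rle(flipped)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit) == 0 || ref_sign == 0) return(NA_real_)
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  epochs$time_axis[post[first]]
}

#' Infer the generative hypothesis from the two-frame regression pattern
#'
#' Runs the pointwise regression on lever-presentation epochs in both value
#' reference frames and applies the frame-discrimination logic: a sustained
#' interaction (>= `min_run` consecutive BH-significant timepoints at
#' `alpha` inside `window_s`) in the chosen frame but not the contralateral
#' frame indicates contralateral-value coding; the reverse pattern indicates
#' chosen-value coding, with versus without a movement component according
#' to whether a sustained choice main effect is present; anything else is
#' indeterminate.
#'
#' @param trials cohort trial table.
#' @param qtraj aligned Q trajectories.
#' @param signals output of [prepare_cohort_signals()].
#' @param window_s,alpha,min_run sustained-significance rule (defaults:
#'   0.25-1 s window, adjusted p < 0.05, 4 consecutive samples).
#' @param random,df_method passed to [pointwise_mixed_regression()];
#'   defaults favour speed on replicated runs.
#' @return a `discrimination_report` list: `inferred`, `evidence`,
#'   `regressions` (both frames).
#' @export
discriminate_frame <- function(trials, qtraj, signals,
                               window_s = c(0.25, 1.0), alpha = 0.05,
                               min_run = 4L, random = "intercept",
                               df_method = "wald") {
  epochs <- cohort_epochs(signals, trials, alignment = "lever_present")
  res <- list()
  for (frame in c("chosen", "contra")) {
    design <- build_pointwise_design(trials, qtraj, frame = frame)
    design <- design[epochs$trial_index_map, , drop = FALSE]
    attr(design, "frame") <- frame
    res[[frame]] <- tryCatch(
      pointwise_mixed_regression(epochs, design, random = random,
                                 df_method = df_method),
      error = function(e) NULL)
  }
  if (is.null(res$chosen) || is.null(res$contra)) {
    return(structure(list(inferred = "indeterminate",
                          evidence = list(error = "regression failure"),
                          regressions = res),
                     class = "discrimination_report"))
  }
  int_chosen <- sustained_significance(res$chosen, "choice:value",
                                       window_s, alpha, min_run)
  int_contra <- sustained_significance(res$contra, "choice:value",
                                       window_s, alpha, min_run)
  choice_main <- sustained_significance(res$chosen, "choice",
                                        window_s, alpha, min_run)
  value_main <- sustained_significance(res$chosen, "value",
                                       window_s, alpha, min_run)
  inferred <- if (int_chosen && !int_contra) {
    "contra_value"
  } else if (int_contra && !int_chosen && choice_main) {
    "chosen_value_plus_movement"
  } else if (int_contra && !int_chosen && !choice_main) {
    "chosen_value"
  } else "indeterminate"
  structure(list(
    inferred = inferred,
    evidence = list(interaction_chosen_frame = int_chosen,
                    interaction_contra_frame = int_contra,
                    choice_main_effect = choice_main,
                    value_main_effect = value_main,
                    window_s = window_s, alpha = alpha, min_run = min_run),
    regressions = res), class = "discrimination_report")
}

#' Run the full synthetic experiment end to end
#'
#' Simulate a cohort on the reversal task, fit the Q-learning model,
#' synthesize photometry under the configured hypothesis, preprocess,
#' run the pointwise regressions (both frames, three alignment events),
#' the multi-event kernel regression, the condition-binned averages, the
#' press-locked selectivity check, and the frame discrimination.
#' Deterministic given `seed`. When `out_dir` is given, writes the trial
#' table, Q trajectories and regression results as CSV plus a JSON summary.
#'
#' @param n_subjects cohort size.
#' @param tconfig a [task_config()].
#' @param pconfig a [photometry_config()].
#' @param fconfig a [fit_config()]; `per_subject_mle` default keeps the
#'   stage fast, hierarchical backends are supported.
#' @param spec a [filter_spec()].
#' @param seed master seed.
#' @param alignments alignment events for the pointwise regressions.
#' @param run_kernels include the multi-event kernel stage.
#' @param out_dir optional output directory.
#' @return a `pipeline_result` list.
#' @export
run_full_pipeline <- function(n_subjects = 17L,
                              tconfig = task_config(trials_per_session = 200L,
                                                    sessions_per_site = 4L),
                              pconfig = photometry_config(),
                              fconfig = fit_config(method = "per_subject_mle"),
                              spec = filter_spec(),
                              seed = 1L,
                              alignments = c("lever_present", "nose_poke",
                                             "lever_press"),
                              run_kernels = TRUE,
                              out_dir = NULL) {
  set.seed(seed)
  params_true <- cohort_params(n_subjects)
  trials <- simulate_cohort(params_true, tconfig)

  fit <- fit_hierarchical(trials, fconfig)
  qtraj <- compute_q_trajectories(fit$subject_params, trials,
                                  tconfig$q_reset_per_session)

  signals <- prepare_cohort_signals(trials, qtraj, pconfig, spec)

  regressions <- list()
  epochs_by_alignment <- list()
  for (al in alignments) {
    ep <- cohort_epochs(signals, trials, alignment = al)
    epochs_by_alignment[[al]] <- ep
    for (frame in c("chosen", "contra")) {
      design <- build_pointwise_design(trials, qtraj, frame = frame)
      design <- design[ep$trial_index_map, , drop = FALSE]
      attr(design, "frame") <- frame
      regressions[[paste(al, frame, sep = "_")]] <-
        pointwise_mixed_regression(ep, design, random = "intercept",
                                   df_method = "wald")
    }
  }

  ep_present <- epochs_by_alignment[["lever_present"]]
  bins_prev <- bin_by_prev_outcome(ep_present, trials)
  bins_dq <- bin_by_dq(ep_present, trials, qtraj)
  crossing <- if ("lever_press" %in% alignments) {
    press_locked_crossing(epochs_by_alignment[["lever_press"]], trials)
  } else NA_real_

  kernels <- if (run_kernels) {
    kernel_regression(lapply(signals, function(sg)
      list(z = sg$z, trials = trials[sg$rows, ],
           session_offsets = sg$session_offsets,
           session_ids = sg$session_ids)))
  } else NULL

  report <- discriminate_frame(trials, qtraj, signals)

  result <- structure(list(
    seed = seed, hypothesis = pconfig$hypothesis, trials = trials,
    fit = fit, qtraj = qtraj, regressions = regressions,
    bins_prev_outcome = bins_prev, bins_dq = bins_dq,
    press_crossing_s = crossing, kernels = kernels,
    discrimination = report, stay_fraction = stay_fraction(trials)),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    data.table::fwrite(qtraj, file.path(out_dir, "qtraj.csv"))
    for (nm in names(regressions))
      data.table::fwrite(regressions[[nm]],
                         file.path(out_dir, paste0("regression_", nm,
                                                   ".csv")))
    jsonlite::write_json(list(
      seed = seed, hypothesis = pconfig$hypothesis,
      inferred = report$inferred, evidence = report$evidence[1:4],
      stay_fraction = result$stay_fraction,
      press_crossing_s = crossing,
      group_percentiles = as.data.frame(fit$group_percentiles)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  result
}
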