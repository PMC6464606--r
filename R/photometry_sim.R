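#' Synthetic photometry generator configuration
#'
#' The generator places calcium-transient-shaped deflections at task events
#' on top of a slowly drifting baseline with white noise, in raw fluorescence
#' units, so the preprocessing chain (high-pass filter, dF/F, z-score) does
#' real work. Event amplitudes follow one of three competing generative
#' hypotheses about value modulation at lever presentation:
#' `"contra_value"` (amplitude proportional to Q_contra - Q_ipsi regardless
#' of choice), `"chosen_value"` (proportional to Q_chosen - Q_unchosen,
#' identical for both choices), and `"chosen_value_plus_movement"` (chosen
#' value plus a fixed bonus on contralateral-choice trials). With
#' `movement_reversal`, the movement component re-expressed at the lever
#' press flips side preference, emulating the post-press reversal of choice
#' selectivity seen when the animal's movement direction reverses.
#'
#' @param hypothesis one of `"contra_value"`, `"chosen_value"`,
#'   `"chosen_value_plus_movement"`.
#' @param value_gain fractional dF/F amplitude per unit of value difference.
#' @param movement_gain fractional dF/F amplitude of the contralateral
#'   movement component.
#' @param movement_reversal flip the side of the movement component at the
#'   lever press.
#' @param kernel_tau_rise,kernel_tau_decay transient time constants (s).
#' @param noise_sd white-noise SD (fraction of baseline).
#' @param drift_amplitude,drift_timescale slow baseline drift SD (fraction of
#'   baseline) and low-pass time constant (s).
#' @param baseline_f baseline raw fluorescence.
#' @param sampling_rate Hz.
#' @return a `photometry_config` list.
#' @export
photometry_config <- function(hypothesis = c("chosen_value_plus_movement",
                                             "chosen_value", "contra_value"),
                              value_gain = 0.05,
                              movement_gain = 0.05,
                              movement_reversal = FALSE,
                              kernel_tau_rise = 0.1,
                              kernel_tau_decay = 0.6,
                              noise_sd = 0.05,
                              drift_amplitude = 0.10,
                              drift_timescale = 60,
                              baseline_f = 100,
                              sampling_rate = 15) {
  hypothesis <- match.arg(hypothesis)
  if (!(kernel_tau_decay > kernel_tau_rise && kernel_tau_rise > 0))
    stop("require kernel_tau_decay > kernel_tau_rise > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (baseline_f <= 0) stop("baseline_f must be > 0", call. = FALSE)
  structure(list(
    hypothesis = hypothesis, value_gain = value_gain,
    movement_gain = movement_gain,
    movement_reversal = isTRUE(movement_reversal),
    kernel_tau_rise = kernel_tau_rise, kernel_tau_decay = kernel_tau_decay,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    drift_timescale = drift_timescale, baseline_f = baseline_f,
    sampling_rate = sampling_rate
  ), class = "photometry_config")
}

#' Unit-peak double-exponential calcium transient kernel
#'
#' `h(t) = exp(-t/tau_decay) - exp(-t/tau_rise)`, normalised to peak 1 and
#' truncated automatically once it has decayed below 1e-3 of the peak.
#'
#' @param config a [photometry_config()] object.
#' @return numeric vector, the impulse response sampled at the config's rate.
#' @export
calcium_kernel <- function(config) {
  tr <- config$kernel_tau_rise; td <- config$kernel_tau_decay
  if (!(td > tr && tr > 0))
    stop("require kernel_tau_decay > kernel_tau_rise > 0", call. = FALSE)
  fs <- config$sampling_rate
  # long enough that exp(-t/td) < 1e-3 * peak
  t_end <- td * (log(1e3) + log(td / (td - tr)) + 1)
  tt <- seq(0, t_end, by = 1 / fs)
  h <- exp(-tt / td) - exp(-tt / tr)
  h <- h / max(h)
  # truncate just past the point where the tail drops below 1e-3 of peak
  tail_start <- which(h < 1e-3 & seq_along(h) > which.max(h))
  h[seq_len(if (length(tail_start)) tail_start[1] else length(h))]
}

#' Noise-free event amplitude under a generative hypothesis
#'
#' @param hypothesis generative hypothesis name.
#' @param choice `"contra"` or `"ipsi"` (vectorised).
#' @param dq_chosen Q(chosen) - Q(unchosen).
#' @param dq_contra Q(contra) - Q(ipsi).
#' @param config a [photometry_config()] object.
#' @return amplitude at lever presentation, fractional dF/F units.
#' @export
trial_amplitude <- function(hypothesis, choice, dq_chosen, dq_contra,
                            config) {
  switch(hypothesis,
    contra_value = config$value_gain * dq_contra,
    chosen_value = config$value_gain * dq_chosen,
    chosen_value_plus_movement =
      config$value_gain * dq_chosen +
      config$movement_gain * as.numeric(choice == "contra"),
    stop("unknown hypothesis: ", hypothesis, call. = FALSE)
  )
}

add_kernel_at <- function(sig, idx, amp, kern) {
  nk <- length(kern); n <- length(sig)
  for (i in seq_along(idx)) {
    k <- idx[i]
    if (is.na(k) || k < 1L || k > n) next
    hi <- min(n, k + nk - 1L)
    len <- hi - k + 1L
    sig[k:hi] <- sig[k:hi] + amp[i] * kern[seq_len(len)]
  }
  sig
}

#' Synthesize a raw-fluorescence photometry trace for one subject
#'
#' Builds, per session, `baseline_f * (1 + drift + events + noise)` where
#' events are calcium-kernel deflections: a value-modulated transient at
#' lever presentation (amplitude from [trial_amplitude()]) and, for the
#' movement-bearing hypothesis, a movement component re-expressed at the
#' lever press (side-flipped when `movement_reversal` is set). Drift is a
#' Gaussian random walk low-pass filtered at `1/drift_timescale` and scaled
#' to `drift_amplitude`, slow enough that the 0.375 Hz high-pass removes it.
#'
#' @param trials one subject's trial table (from [simulate_subject()]).
#' @param qtraj matching rows of a Q-trajectory table (needs `dq_chosen`,
#'   `dq_contra`); see [compute_q_trajectories()].
#' @param config a [photometry_config()] object.
#' @return a `photometry_trace` list: `site_id`, `sampling_rate`, `samples`,
#'   `session_offsets` (1-based start sample of each session),
#'   `session_ids`.
#' @export
synthesize_trace <- function(trials, qtraj, config) {
  if (nrow(trials) != nrow(qtraj))
    stop("trials and qtraj are not aligned trial-for-trial", call. = FALSE)
  fs <- config$sampling_rate
  kern <- calcium_kernel(config)
  sessions <- unique(trials$session_id)
  samples <- numeric(0)
  offsets <- integer(0)
  for (ses in sessions) {
    sel <- trials$session_id == ses
    tr <- trials[sel, ]
    qt <- qtraj[sel, ]
    t_end <- max(tr$t_outcome, tr$t_lever_present, na.rm = TRUE) + 5
    n <- ceiling(t_end * fs) + 1L
    ev <- numeric(n)

    amp <- trial_amplitude(config$hypothesis, tr$choice,
                           qt$dq_chosen, qt$dq_contra, config)
    amp[is.na(amp)] <- 0
    idx_present <- round(tr$t_lever_present * fs) + 1L
    ev <- add_kernel_at(ev, idx_present, amp, kern)

    if (config$hypothesis == "chosen_value_plus_movement") {
      side <- if (config$movement_reversal) "ipsi" else "contra"
      amp_press <- config$movement_gain * as.numeric(tr$choice == side)
      amp_press[is.na(amp_press)] <- 0
      idx_press <- round(tr$t_lever_press * fs) + 1L
      ev <- add_kernel_at(ev, idx_press, amp_press, kern)
    }

    if (config$drift_amplitude > 0) {
      a <- exp(-1 / (fs * config$drift_timescale))
      walk <- stats::filter(rnorm(n), a, method = "recursive")
      walk <- as.numeric(walk)
      s <- sd(walk)
      drift <- if (s > 0) walk / s * config$drift_amplitude else numeric(n)
    } else drift <- numeric(n)

    noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd)
             else numeric(n)

    offsets <- c(offsets, length(samples) + 1L)
    samples <- c(samples, config$baseline_f * (1 + drift + ev + noise))
  }
  structure(list(site_id = trials$site_id[1], sampling_rate = fs,
                 samples = samples, session_offsets = offsets,
                 session_ids = sessions),
            class = "photometry_trace")
}

#' Global event times on a concatenated trace
#'
#' Maps within-session event timestamps to seconds on the concatenated
#' record of a [synthesize_trace()] trace.
#'
#' @param trace a `photometry_trace`.
#' @param session_id per-event session identifiers.
#' @param t_event per-event timestamps, seconds from session start.
#' @return numeric vector of global times (s).
#' @export
global_event_times <- function(trace, session_id, t_event) {
  off <- setNames(trace$session_offsets, trace$session_ids)
  (off[as.character(session_id)] - 1) / trace$sampling_rate + t_event
}
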