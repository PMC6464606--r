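#' High-pass filter specification for photometry preprocessing
#'
#' Defaults are the preprocessing constants used throughout: passband edge
#' 0.375 Hz, stopband edge 0.075 Hz, at least 10 dB stopband attenuation,
#' 15 Hz sampling.
#'
#' @param passband_hz,stopband_hz band edges (Hz); `0 < stopband < passband
#'   < fs/2`.
#' @param stopband_atten_db minimum attenuation at the stopband edge (dB).
#' @param sampling_rate Hz.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(passband_hz = 0.375, stopband_hz = 0.075,
                        stopband_atten_db = 10, sampling_rate = 15) {
  if (!(stopband_hz > 0 && stopband_hz < passband_hz &&
        passband_hz < sampling_rate / 2))
    stop("require 0 < stopband_hz < passband_hz < sampling_rate/2",
         call. = FALSE)
  if (stopband_atten_db <= 0)
    stop("stopband_atten_db must be > 0", call. = FALSE)
  structure(list(passband_hz = passband_hz, stopband_hz = stopband_hz,
                 stopband_atten_db = stopband_atten_db,
                 sampling_rate = sampling_rate), class = "filter_spec")
}

#' Magnitude response of an FIR filter
#'
#' @param b FIR coefficients.
#' @param f frequencies (Hz).
#' @param fs sampling rate (Hz).
#' @return |H(f)| at each frequency.
#' @export
fir_response <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(fi)
    Mod(sum(b * exp(-2i * pi * fi * k / fs))), numeric(1))
}

#' Design the high-pass FIR filter
#'
#' Linear-phase (type I) Hamming-window design with the cutoff at the
#' midpoint of the transition band. The order starts at the Hamming
#' transition-width estimate `3.3 / ((passband - stopband)/fs)` and is
#' increased until the magnitude response is at least
#' `stopband_atten_db` down at the stopband edge and within +/- 1 dB of
#' unity from the passband edge to Nyquist.
#'
#' @param spec a [filter_spec()] object.
#' @return numeric coefficient vector with attributes `spec` and `order`.
#' @export
design_highpass_fir <- function(spec) {
  fs <- spec$sampling_rate
  wc <- (spec$passband_hz + spec$stopband_hz) / 2 / (fs / 2)
  n <- ceiling(3.3 / ((spec$passband_hz - spec$stopband_hz) / fs))
  n <- n + n %% 2  # even order -> odd length, type I (valid high-pass)
  f_pass <- seq(spec$passband_hz, fs / 2, length.out = 200)
  repeat {
    b <- signal::fir1(n, wc, type = "high")
    att_db <- -20 * log10(fir_response(b, spec$stopband_hz, fs))
    pass_db <- 20 * log10(fir_response(b, f_pass, fs))
    if (att_db >= spec$stopband_atten_db && all(abs(pass_db) <= 1)) break
    n <- n + 16L
    if (n > 2000L)
      stop("unattainable filter specification at this sampling rate",
           call. = FALSE)
  }
  structure(as.numeric(b), spec = spec, order = n)
}

filtfilt_fir <- function(b, x) {
  nb <- length(b); n <- length(x)
  k <- min(3L * nb, n - 1L)
  xe <- c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
  y <- stats::filter(xe, b, method = "convolution", sides = 1)
  y <- rev(as.numeric(y))
  y <- stats::filter(y, b, method = "convolution", sides = 1)
  y <- rev(as.numeric(y))
  y[(k + 1):(k + n)]
}

#' Apply an FIR filter with zero phase
#'
#' Forward-backward application (so event-locked features are not delayed)
#' with odd-reflection edge padding, applied independently to each session
#' segment of a trace so that filtering and session concatenation commute.
#'
#' @param trace a `photometry_trace` or a plain numeric series.
#' @param b FIR coefficients from [design_highpass_fir()].
#' @param causal single forward pass instead of zero-phase.
#' @return filtered series (numeric), same length as the input samples.
#' @export
apply_filter <- function(trace, b, causal = FALSE) {
  segments <- if (inherits(trace, "photometry_trace")) {
    bounds <- c(trace$session_offsets, length(trace$samples) + 1L)
    lapply(seq_along(trace$session_offsets), function(i)
      trace$samples[bounds[i]:(bounds[i + 1L] - 1L)])
  } else list(as.numeric(trace))
  out <- lapply(segments, function(x) {
    if (length(x) <= 3L * length(b))
      stop("trace segment shorter than 3x the filter length", call. = FALSE)
    if (causal) {
      y <- stats::filter(c(rep(x[1], length(b) - 1L), x), b,
                         method = "convolution", sides = 1)
      as.numeric(y)[length(b):(length(b) - 1L + length(x))]
    } else filtfilt_fir(b, x)
  })
  unlist(out, use.names = FALSE)
}

#' Fractional fluorescence change (dF/F)
#'
#' The high-pass-filtered signal divided by the mean of the raw signal
#' before filtering, the mean taken over the site's full concatenated
#' record.
#'
#' @param raw raw fluorescence series (full record).
#' @param filtered high-pass-filtered series.
#' @return dF/F series.
#' @export
compute_dff <- function(raw, filtered) {
  m <- mean(raw)
  if (!is.finite(m) || m <= 0)
    stop("mean of raw signal must be positive", call. = FALSE)
  filtered / m
}

#' Z-score a site's dF/F over the full record
#'
#' @param dff dF/F series for one recording site.
#' @return z-scored series (mean 0, SD 1 over the record).
#' @export
zscore_site <- function(dff) {
  s <- sd(dff)
  if (!is.finite(s) || s == 0)
    stop("zero-variance series cannot be z-scored", call. = FALSE)
  (dff - mean(dff)) / s
}

#' Preprocess a raw trace: filter, dF/F, z-score
#'
#' @param trace a `photometry_trace`.
#' @param spec a [filter_spec()] object.
#' @param b optional pre-designed coefficients (designed from `spec` if
#'   omitted).
#' @return list `z` (z-scored dF/F series), `dff`, `filtered`, `b`.
#' @export
preprocess_trace <- function(trace, spec = filter_spec(), b = NULL) {
  if (is.null(b)) b <- design_highpass_fir(spec)
  filtered <- apply_filter(trace, b)
  dff <- compute_dff(trace$samples, filtered)
  list(z = zscore_site(dff), dff = dff, filtered = filtered, b = b)
}

#' Extract event-locked epochs on the 15 Hz grid
#'
#' Each event is aligned to the nearest sample; the epoch covers 15 samples
#' before the event and 30 from the event onward (45 samples, 1 s before to
#' 2 s after). Events whose window exceeds the series bounds, or crosses a
#' session boundary when `session_offsets` is given, are dropped and
#' reported, never padded.
#'
#' @param z preprocessed (z-scored) series.
#' @param event_times_s event times in seconds on the series' clock.
#' @param fs sampling rate (Hz).
#' @param session_offsets optional 1-based session start indices.
#' @param alignment_event label stored in the result.
#' @param pre,post samples before / from the event.
#' @return an `epoch_matrix`: `values` (kept trials x 45), `time_axis`
#'   (seconds, `-1, ..., +1.933`), `trial_index_map` (indices of kept
#'   events), `dropped` (indices of dropped events), `alignment_event`.
#' @export
extract_epochs <- function(z, event_times_s, fs = 15,
                           session_offsets = NULL,
                           alignment_event = "lever_present",
                           pre = 15L, post = 30L) {
  if (length(event_times_s) == 0)
    stop("empty event list", call. = FALSE)
  n <- length(z)
  centers <- round(event_times_s * fs) + 1L
  lo <- centers - pre
  hi <- centers + post - 1L
  ok <- !is.na(centers) & lo >= 1L & hi <= n
  if (!is.null(session_offsets)) {
    seg <- findInterval(centers, session_offsets)
    seg_lo <- findInterval(lo, session_offsets)
    seg_hi <- findInterval(hi, session_offsets)
    ok <- ok & !is.na(seg) & seg_lo == seg & seg_hi == seg
  }
  kept <- which(ok)
  vals <- matrix(NA_real_, length(kept), pre + post)
  for (i in seq_along(kept))
    vals[i, ] <- z[(centers[kept[i]] - pre):(centers[kept[i]] + post - 1L)]
  structure(list(
    values = vals,
    time_axis = (seq_len(pre + post) - pre - 1L) / fs,
    alignment_event = alignment_event,
    trial_index_map = kept,
    dropped = which(!ok)
  ), class = "epoch_matrix")
}
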