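#' Event-locked skin-conductance amplitude
#'
#' For each onset, the base-to-peak amplitude within a `window_s`-second
#' window: maximum of the trace in the window minus the trace value at the
#' window start ("base"), floored at 0 per event; the mean across onsets
#' is returned.
#'
#' @param trace An `scr_trace`.
#' @param onsets Event onsets in seconds.
#' @param window_s Window length in seconds (default 15).
#' @return Mean base-to-peak amplitude in uS.
#' @export
scr_event_amplitude <- function(trace, onsets, window_s = 15) {
  fs <- trace$sampling_rate
  n <- length(trace$samples)
  amps <- vapply(onsets, function(on) {
    i0 <- floor(on * fs) + 1
    i1 <- floor((on + window_s) * fs)
    if (i0 < 1 || i1 > n)
      stop("onset at ", on, " s (+", window_s, " s) outside trace")
    w <- trace$samples[i0:i1]
    max(0, max(w) - w[1])
  }, numeric(1))
  mean(amps)
}

#' Mean heart rate from an RR series
#' @param rr An `rr_series`.
#' @return Heart rate in beats/min (`60000 / mean(RR ms)`).
#' @export
mean_heart_rate <- function(rr) {
  if (length(rr$rr) == 0) stop("empty RR series")
  60000 / mean(rr$rr)
}

# evenly resampled tachogram: RR (ms) as a function of beat time (s)
rr_tachogram <- function(rr, resample_fs = 4) {
  t_beat <- cumsum(rr$rr) / 1000
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / resample_fs)
  sp <- spline(t_beat, rr$rr, xout = grid, method = "fmm")
  list(t = grid, rr = sp$y, fs = resample_fs)
}

#' High-frequency heart-rate-variability power
#'
#' Resamples the RR series to an evenly spaced tachogram (default 4 Hz,
#' cubic spline), removes a linear trend, estimates the one-sided
#' periodogram and integrates the power over the HF band
#' (default 0.15-0.40 Hz). Units: ms^2.
#'
#' @param rr An `rr_series` covering at least `min_duration_s` seconds.
#' @param band HF band in Hz.
#' @param resample_fs Tachogram sampling rate, Hz.
#' @param min_duration_s Minimum series duration (default 120 s).
#' @return HF power in ms^2.
#' @export
hf_power <- function(rr, band = c(0.15, 0.40), resample_fs = 4,
                     min_duration_s = 120) {
  dur <- sum(rr$rr) / 1000
  if (dur < min_duration_s)
    stop("RR series too short (", round(dur), " s < ", min_duration_s, " s)")
  tg <- rr_tachogram(rr, resample_fs)
  x <- tg$rr
  n <- length(x)
  x <- x - lm.fit(cbind(1, seq_len(n)), x)$fitted.values
  X <- fft(x)
  # one-sided power spectral density, ms^2 per Hz
  psd <- (2 / (n * tg$fs)) * Mod(X[seq_len(floor(n / 2) + 1)])^2
  psd[1] <- psd[1] / 2
  freqs <- (seq_along(psd) - 1) * tg$fs / n
  df <- tg$fs / n
  sum(psd[freqs >= band[1] & freqs <= band[2]]) * df
}

#' Short-term detrended fluctuation analysis exponent (DFA alpha-1)
#'
#' Integrates the mean-centered RR series, splits the profile into
#' non-overlapping boxes of each scale (default 4-16 beats), computes the
#' root-mean-square residual around a per-box linear fit, `F(n)`, and
#' returns the least-squares slope of `log F(n)` versus `log n`. White
#' noise gives ~0.5, 1/f (pink) fluctuations ~1.0, anti-correlated series
#' < 0.5.
#'
#' @param rr An `rr_series` (or plain numeric series via `rr_series()`),
#'   length at least `4 * max(scales)`.
#' @param scales Integer box sizes in beats (default `4:16`).
#' @return The scaling exponent alpha-1.
#' @export
dfa_alpha1 <- function(rr, scales = 4:16) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  n <- length(x)
  if (n < 4 * max(scales))
    stop("series too short for DFA: need >= ", 4 * max(scales), " beats")
  y <- cumsum(x - mean(x))
  Fn <- vapply(scales, function(bs) {
    nb <- floor(n / bs)
    idx <- seq_len(nb * bs)
    seg <- matrix(y[idx], nrow = bs)
    t <- seq_len(bs)
    X <- cbind(1, t)
    H <- X %*% solve(crossprod(X), t(X))
    resid <- seg - H %*% seg
    sqrt(mean(resid^2))
  }, numeric(1))
  unname(coef(lm.fit(cbind(1, log(scales)), log(Fn)))[2])
}

#' Autonomic index panel for one subject
#'
#' Computes the four indices in one tidy row set: event-locked SCR
#' amplitude per condition, mean heart rate, HF power and DFA alpha-1.
#'
#' @param rr An `rr_series`.
#' @param scr_traces Named list of `scr_trace` objects per condition.
#' @param designs Named list of matching `block_design`s.
#' @param scr_window_s SCR window, seconds.
#' @return Tibble `index`, `condition`, `value`.
#' @export
autonomic_indices <- function(rr, scr_traces, designs, scr_window_s = 15) {
  scr_rows <- purrr::imap_dfr(scr_traces, function(trace, cond) {
    d <- designs[[cond]]
    onsets <- d$events$onset[d$events$condition %in%
                               c(OT_CONDITIONS, unname(REST_OF))]
    tibble::tibble(index = "scr_amplitude", condition = cond,
                   value = scr_event_amplitude(trace, onsets, scr_window_s))
  })
  dplyr::bind_rows(
    scr_rows,
    tibble::tibble(index = c("heart_rate", "hf_power", "dfa_alpha1"),
                   condition = NA_character_,
                   value = c(mean_heart_rate(rr), hf_power(rr),
                             dfa_alpha1(rr)))
  )
}
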