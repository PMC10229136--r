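#' Build an alternating block stimulation design
#'
#' Constructs one session of the block paradigm: `n_blocks` stimulation
#' blocks of `stim_s` seconds, each followed by a rest interval of `rest_s`
#' seconds. The default session (20 blocks of 30 s + 15 s rest) lasts
#' 900 s (15 min). Rest intervals carry their own condition label
#' (`rest_after_touch` / `rest_after_massage`) because they enter the GLM
#' as explicit regressors.
#'
#' @param n_blocks Number of stimulation blocks (>= 0).
#' @param stim_s Stimulation block duration, seconds.
#' @param rest_s Rest interval duration, seconds.
#' @param sampling_rate Sampling rate in Hz that recordings of this session
#'   use (default 6.78).
#' @param condition Stimulation condition label, `"gentle_touch"` or
#'   `"medium_massage"`.
#' @return A `block_design`: list with `events` (tibble: `condition`,
#'   `onset`, `duration`, seconds) and `sampling_rate`.
#' @examples
#' d <- make_block_design()
#' design_duration(d) # 900
#' @export
make_block_design <- function(n_blocks = 20, stim_s = 30, rest_s = 15,
                              sampling_rate = 6.78,
                              condition = c("gentle_touch", "medium_massage")) {
  condition <- match.arg(condition)
  if (n_blocks < 0) stop("n_blocks must be >= 0")
  if (stim_s <= 0 || rest_s <= 0) stop("stim_s and rest_s must be > 0")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  rest_label <- REST_OF[[condition]]
  if (n_blocks == 0) {
    events <- tibble::tibble(condition = character(), onset = numeric(),
                             duration = numeric())
  } else {
    k <- seq_len(n_blocks) - 1
    cycle <- stim_s + rest_s
    events <- tibble::tibble(
      condition = rep(c(condition, rest_label), n_blocks),
      onset = as.numeric(rbind(k * cycle, k * cycle + stim_s)),
      duration = rep(c(stim_s, rest_s), n_blocks)
    )
  }
  structure(list(events = events, sampling_rate = sampling_rate),
            class = "block_design")
}

#' Total duration of a block design in seconds
#' @param design A `block_design`.
#' @return Duration in seconds (end of the last event; 0 for an empty design).
#' @export
design_duration <- function(design) {
  ev <- design$events
  if (nrow(ev) == 0) return(0)
  max(ev$onset + ev$duration)
}

#' Number of samples a recording of this design has
#' @param design A `block_design`.
#' @return Integer sample count, `floor(duration * sampling_rate)`.
#' @export
design_n_samples <- function(design) {
  as.integer(floor(design_duration(design) * design$sampling_rate))
}

#' Concatenate block designs into one session-spanning design
#'
#' Later designs are shifted in time so the sessions are laid end to end,
#' optionally separated by `gap_s` seconds of unmodeled time. Used to fit a
#' single GLM with all four task regressors over both touch sessions.
#'
#' @param ... `block_design` objects with a common sampling rate.
#' @param gap_s Gap between consecutive sessions, seconds.
#' @return A `block_design` covering all sessions.
#' @export
concat_designs <- function(..., gap_s = 0) {
  ds <- list(...)
  if (length(ds) == 1 && is.list(ds[[1]]) && !inherits(ds[[1]], "block_design"))
    ds <- ds[[1]]
  stopifnot(length(ds) >= 1, all(vapply(ds, inherits, TRUE, "block_design")))
  fs <- unique(vapply(ds, function(d) d$sampling_rate, 1))
  if (length(fs) != 1) stop("sampling rates differ across designs")
  offset <- 0
  evs <- vector("list", length(ds))
  for (i in seq_along(ds)) {
    ev <- ds[[i]]$events
    ev$onset <- ev$onset + offset
    evs[[i]] <- ev
    offset <- offset + design_duration(ds[[i]]) + gap_s
  }
  structure(list(events = dplyr::bind_rows(evs), sampling_rate = fs),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat("<block_design> ", nrow(x$events), " events, ",
      design_duration(x), " s @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF — a positive gamma peaking at
#' `peak_delay` seconds minus a later gamma undershoot scaled by
#' `1/ratio` — on the recording's time grid, truncated at `duration_s`
#' and normalized to a peak value of 1. Gamma shapes are chosen so the
#' mode of each component sits exactly at its stated delay.
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param hrf_params List with `peak_delay` (s, default 6),
#'   `undershoot_delay` (s, default 16), `peak_dispersion`,
#'   `undershoot_dispersion` (s, default 1) and `ratio`
#'   (peak:undershoot, default 6).
#' @param duration_s Kernel length in seconds (default 32).
#' @return Numeric kernel sampled at `1/sampling_rate` steps starting at t=0.
#' @examples
#' h <- canonical_hrf(6.78)
#' which.max(h) / 6.78 # ~6 s
#' @export
canonical_hrf <- function(sampling_rate, hrf_params = default_hrf_params(),
                          duration_s = 32) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  p <- utils::modifyList(default_hrf_params(), hrf_params %||% list())
  t <- seq(0, duration_s, by = 1 / sampling_rate)
  # shape = delay/dispersion + 1 puts the gamma mode at `delay`
  h <- dgamma(t, shape = p$peak_delay / p$peak_dispersion + 1,
              rate = 1 / p$peak_dispersion) -
    dgamma(t, shape = p$undershoot_delay / p$undershoot_dispersion + 1,
           rate = 1 / p$undershoot_dispersion) / p$ratio
  h / max(h)
}

#' Default canonical HRF parameters
#' @return List of double-gamma parameters (seconds; ratio dimensionless).
#' @export
default_hrf_params <- function() {
  list(peak_delay = 6, undershoot_delay = 16,
       peak_dispersion = 1, undershoot_dispersion = 1, ratio = 6)
}

# condition drive on the sample grid: 1 during blocks, optional exponential
# tail of time constant tau (s) after each offset
condition_drive <- function(design, condition, tau = 0) {
  n <- design_n_samples(design)
  fs <- design$sampling_rate
  t <- (seq_len(n) - 1) / fs
  drive <- numeric(n)
  ev <- design$events[design$events$condition == condition, ]
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset[i]; off <- ev$onset[i] + ev$duration[i]
    drive[t >= on & t < off] <- 1
    if (tau > 0) {
      post <- t >= off
      drive[post] <- drive[post] + exp(-(t[post] - off) / tau)
    }
  }
  # overlapping tails saturate at full drive
  pmin(drive, 1)
}

# convolve a drive with the area-normalized canonical HRF so a sustained
# block plateaus at the drive amplitude (beta = response amplitude in uM)
convolve_hrf <- function(drive, sampling_rate, hrf_params = default_hrf_params()) {
  h <- canonical_hrf(sampling_rate, hrf_params)
  h <- h / sum(h)
  out <- convolve(drive, rev(h), type = "open")
  out[seq_along(drive)]
}

#' Build a first-level GLM design matrix
#'
#' One HRF-convolved regressor per task condition, in the fixed order
#' `medium_massage`, `gentle_touch`, `rest_after_massage`,
#' `rest_after_touch`, followed by an intercept. Conditions absent from the
#' design yield an all-zero column, which [fit_glm()] drops with a message.
#' Boxcars are convolved with the canonical double-gamma kernel normalized
#' to unit area, so a sustained response of amplitude A yields a beta of A.
#'
#' @param block_design A `block_design` (possibly concatenated sessions).
#' @param sampling_rate Sampling rate; defaults to the design's.
#' @param hrf_params See [canonical_hrf()].
#' @return A `design_matrix`: list with `values` (samples x regressors
#'   matrix, named columns), `sampling_rate`, `hrf_params`.
#' @export
build_design <- function(block_design, sampling_rate = NULL,
                         hrf_params = default_hrf_params()) {
  if (nrow(block_design$events) == 0) stop("empty block design")
  fs <- sampling_rate %||% block_design$sampling_rate
  bd <- block_design
  bd$sampling_rate <- fs
  labels <- c("medium_massage", "gentle_touch",
              "rest_after_massage", "rest_after_touch")
  n <- design_n_samples(bd)
  X <- vapply(labels, function(cond) {
    convolve_hrf(condition_drive(bd, cond), fs, hrf_params)
  }, numeric(n))
  X <- cbind(X, intercept = 1)
  structure(list(values = X, sampling_rate = fs, hrf_params = hrf_params),
            class = "design_matrix")
}
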