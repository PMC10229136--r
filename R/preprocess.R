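#' Preprocessing configuration
#'
#' Collects the constants of the optical conversion and filtering chain.
#' Extinction coefficients default to the Gratzer/Cope compilation used by
#' standard fNIRS toolchains, in cm^-1 mM^-1 at 760 and 850 nm; the
#' differential pathlength factor (DPF) defaults to 6.0 at both
#' wavelengths, a common adult-head value. All are overridable.
#'
#' @param wavelengths Two wavelengths in nm.
#' @param extinction 2x2 matrix, rows = wavelengths, columns = c(HbO, HbR),
#'   units cm^-1 mM^-1.
#' @param dpf Differential pathlength factor per wavelength (dimensionless).
#' @param distance Source-detector separation in cm.
#' @param detrend_order Polynomial detrend order (default 1, linear).
#' @param band Bandpass edges in Hz (default 0.01-0.08).
#' @param filter_order Butterworth order (default 4), applied
#'   forward-backward (zero phase).
#' @param tddr_tuning Tukey biweight tuning constant for motion repair.
#' @param tddr_split_freq Low/high split frequency in Hz for motion repair
#'   (`NULL` = weight the full-band derivative).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(wavelengths = c(760, 850),
                              extinction = default_extinction(),
                              dpf = c(6, 6),
                              distance = 3,
                              detrend_order = 1,
                              band = c(0.01, 0.08),
                              filter_order = 4,
                              tddr_tuning = 4.685,
                              tddr_split_freq = 0.5) {
  extinction <- as.matrix(extinction)
  if (any(dim(extinction) != c(2, 2))) stop("extinction must be 2x2")
  if (abs(det(extinction)) < 1e-12) stop("extinction matrix is singular")
  if (band[1] <= 0 || band[2] <= band[1]) stop("invalid band")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 dpf = dpf, distance = distance,
                 detrend_order = detrend_order, band = band,
                 filter_order = filter_order, tddr_tuning = tddr_tuning,
                 tddr_split_freq = tddr_split_freq),
            class = "preprocess_config")
}

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction of oxy- and deoxyhemoglobin at 760 and 850 nm from the
#' Gratzer/Cope spectra compilation, in cm^-1 mM^-1.
#'
#' @return 2x2 matrix, rows `w760`/`w850`, columns `HbO`/`HbR`.
#' @export
default_extinction <- function() {
  matrix(c(1.4866, 3.8437,
           2.5264, 1.7986),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("w760", "w850"), c("HbO", "HbR")))
}

#' Convert raw intensity to optical density
#'
#' Per channel, `OD(t) = -log(I(t) / mean(I))`: optical density change
#' relative to the channel's mean intensity (natural log).
#'
#' @param recording An `fnirs_recording` with `signal_kind = "intensity"`,
#'   strictly positive values.
#' @return The recording with `signal_kind = "od"`.
#' @export
intensity_to_od <- function(recording) {
  if (recording$signal_kind != "intensity")
    stop("expected an intensity recording, got ", recording$signal_kind)
  if (any(recording$data <= 0)) stop("non-positive intensities")
  out <- map_channels(recording, function(x) -log(x / mean(x)))
  out$signal_kind <- "od"
  out
}

#' Modified Beer-Lambert conversion to chromophore concentrations
#'
#' Solves, per channel and sample, the two-wavelength extinction system
#' `dOD = E . dc * dpf * distance` for the concentration changes of HbO and
#' HbR. With two wavelengths the system is exactly determined; the
#' least-squares form `(E'E)^-1 E'` is used so an overdetermined extinction
#' table would also work. Output is in micromolar (extinction in
#' cm^-1 mM^-1, distance in cm).
#'
#' @param od_pair List of two optical-density `fnirs_recording`s, in the
#'   order of `config$wavelengths`.
#' @param config A [preprocess_config()].
#' @return Named list with `HbO` and `HbR` concentration recordings (uM).
#' @export
mbll <- function(od_pair, config = preprocess_config()) {
  stopifnot(length(od_pair) == 2)
  for (r in od_pair) {
    if (r$signal_kind != "od") stop("mbll expects optical-density input")
  }
  if (!all(dim(od_pair[[1]]$data) == dim(od_pair[[2]]$data)))
    stop("mismatched channel sets between wavelengths")
  E <- config$extinction
  # per-wavelength pathlength scaling folded into the system matrix
  L <- config$dpf * config$distance
  A <- E * L # row i scaled by dpf_i * d
  pinv <- solve(crossprod(A), t(A))
  n_ch <- nrow(od_pair[[1]]$data)
  n_s <- ncol(od_pair[[1]]$data)
  hbo <- matrix(0, n_ch, n_s, dimnames = dimnames(od_pair[[1]]$data))
  hbr <- hbo
  for (ch in seq_len(n_ch)) {
    od <- rbind(od_pair[[1]]$data[ch, ], od_pair[[2]]$data[ch, ])
    conc <- pinv %*% od # mM
    hbo[ch, ] <- conc[1, ] * 1000 # -> uM
    hbr[ch, ] <- conc[2, ] * 1000
  }
  fs <- od_pair[[1]]$sampling_rate
  mont <- od_pair[[1]]$montage
  list(
    HbO = fnirs_recording(hbo, fs, "concentration", chromophore = "HbO",
                          montage = mont),
    HbR = fnirs_recording(hbr, fs, "concentration", chromophore = "HbR",
                          montage = mont)
  )
}

#' Forward Beer-Lambert model (concentrations to optical density)
#'
#' The exact inverse of [mbll()]: maps HbO/HbR concentration changes (uM)
#' to the optical-density pair. Used to exercise the conversion stage on
#' synthetic data and for round-trip testing.
#'
#' @param hbo,hbr Concentration `fnirs_recording`s in uM.
#' @param config A [preprocess_config()].
#' @return List of two `od` recordings, in `config$wavelengths` order.
#' @export
forward_mbll <- function(hbo, hbr, config = preprocess_config()) {
  A <- config$extinction * (config$dpf * config$distance)
  ods <- lapply(1:2, function(i) {
    od <- (A[i, 1] * hbo$data + A[i, 2] * hbr$data) / 1000
    fnirs_recording(od, hbo$sampling_rate, "od",
                    wavelength = config$wavelengths[i], montage = hbo$montage)
  })
  names(ods) <- paste0("w", config$wavelengths)
  ods
}

#' Polynomial detrending
#'
#' Per channel, subtracts the least-squares polynomial fit of the given
#' order; order 0 removes the mean, order 1 (the default used by the
#' pipeline) removes linear drift.
#'
#' @param recording An `fnirs_recording`.
#' @param order Polynomial order (>= 0).
#' @return Detrended recording.
#' @export
polynomial_detrend <- function(recording, order = 1) {
  if (order < 0) stop("order must be >= 0")
  n <- ncol(recording$data)
  if (n <= order + 1) stop("too few samples for detrend order ", order)
  X <- matrix(1, n, 1)
  if (order >= 1) {
    P <- stats::poly(seq_len(n) / n, degree = order, raw = FALSE)
    X <- cbind(X, P[, seq_len(order), drop = FALSE])
  }
  # orthonormalize once; projection = X (X'X)^-1 X' y via qr
  Q <- qr.Q(qr(X))
  out <- recording
  fitted <- Q %*% (t(Q) %*% t(recording$data))
  out$data <- recording$data - t(fitted)
  dimnames(out$data) <- dimnames(recording$data)
  out
}

# single-channel temporal derivative distribution repair
tddr_channel <- function(x, fs, tune = 4.685, split_freq = 0.5, max_iter = 50) {
  n <- length(x)
  if (n < 3) stop("tddr needs at least 3 samples")
  mu_x <- mean(x)
  xc <- x - mu_x
  if (!is.null(split_freq) && split_freq * 2 / fs < 1) {
    bf <- signal::butter(3, split_freq * 2 / fs, type = "low")
    low <- signal::filtfilt(bf, xc)
  } else {
    low <- xc
  }
  high <- xc - low
  deriv <- diff(low)
  w <- rep(1, length(deriv))
  mu <- Inf
  eps_d <- sqrt(.Machine$double.eps)
  for (iter in seq_len(max_iter)) {
    mu0 <- mu
    mu <- sum(w * deriv) / sum(w)
    dev <- abs(deriv - mu)
    sigma <- 1.4826 * median(dev)
    if (sigma == 0) {
      # degenerate scale: most derivative samples identical; keep those,
      # zero out any deviating (artifact) samples
      w <- as.numeric(dev == 0)
      if (sum(w) == 0) w <- rep(1, length(deriv))
      mu <- if (any(w > 0)) sum(w * deriv) / sum(w) else mu
      break
    }
    r <- dev / (sigma * tune)
    w <- ((1 - r^2) * (r < 1))^2
    if (is.finite(mu0) && abs(mu - mu0) < eps_d * max(abs(mu), abs(mu0)))
      break
  }
  low_c <- cumsum(c(0, w * (deriv - mu)))
  low_c <- low_c - mean(low_c)
  low_c + high + mu_x
}

#' Temporal derivative distribution repair (TDDR) motion correction
#'
#' Robust motion-artifact removal: the signal's low-frequency component
#' (below `split_freq`) is differentiated, the derivative samples are
#' iteratively reweighted with Tukey's biweight on robustly centered and
#' scaled residuals until the weighted mean converges, and the weighted
#' derivative is re-integrated; the untouched high-frequency component is
#' then restored. Motion spikes and baseline steps produce outlying
#' derivative samples and are suppressed; artifact-free signal passes
#' through nearly unchanged.
#'
#' Note that with the conventional 0.5 Hz split, artifacts much briefer
#' than ~2 s retain their high-frequency residue; pass `split_freq = NULL`
#' to reweight the full-band derivative when sub-second spikes must be
#' removed and no cardiac-band signal needs preserving.
#'
#' @param recording An `fnirs_recording`.
#' @param tune Tukey biweight tuning constant (default 4.685).
#' @param split_freq Low/high split frequency in Hz; `NULL` for full band.
#' @param max_iter Maximum reweighting iterations.
#' @return Corrected recording.
#' @export
tddr <- function(recording, tune = 4.685, split_freq = 0.5, max_iter = 50) {
  map_channels(recording, tddr_channel, fs = recording$sampling_rate,
               tune = tune, split_freq = split_freq, max_iter = max_iter)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Per channel, applies an IIR Butterworth bandpass (default 0.01-0.08 Hz)
#' forward and backward (`filtfilt`), giving zero phase shift and doubling
#' the effective attenuation.
#'
#' @param recording An `fnirs_recording`.
#' @param band Passband edges in Hz.
#' @param filter_order Butterworth design order (default 4).
#' @return Filtered recording.
#' @export
bandpass <- function(recording, band = c(0.01, 0.08), filter_order = 4) {
  nyq <- recording$sampling_rate / 2
  if (band[1] <= 0 || band[2] >= nyq || band[2] <= band[1])
    stop("band must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(filter_order, band / nyq, type = "pass")
  map_channels(recording, function(x) signal::filtfilt(bf, x))
}

#' Run the full preprocessing chain on a concentration recording
#'
#' Fixed stage order: polynomial detrend, TDDR motion correction, zero-phase
#' Butterworth bandpass. (Optical conversion — [intensity_to_od()] then
#' [mbll()] — precedes this chain when starting from raw intensity.)
#'
#' @param recording A concentration `fnirs_recording`.
#' @param config A [preprocess_config()].
#' @param stages Character subset of `c("detrend", "tddr", "bandpass")` to
#'   run, in the fixed order.
#' @return Preprocessed recording.
#' @export
preprocess <- function(recording, config = preprocess_config(),
                       stages = c("detrend", "tddr", "bandpass")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- recording
  if ("detrend" %in% stages)
    out <- polynomial_detrend(out, config$detrend_order)
  if ("tddr" %in% stages)
    out <- tddr(out, tune = config$tddr_tuning,
                split_freq = config$tddr_split_freq)
  if ("bandpass" %in% stages)
    out <- bandpass(out, config$band, config$filter_order)
  out
}
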