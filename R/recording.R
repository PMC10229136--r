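#' fNIRS recording container
#'
#' A channel-by-sample matrix of fNIRS data plus the metadata the pipeline
#' tracks through every stage: sampling rate, what physical quantity the
#' values are (`signal_kind`: `"intensity"`, `"od"` for optical density, or
#' `"concentration"` in micromolar), which chromophore (for concentration
#' data) or wavelength in nm (for intensity / optical density data), and the
#' montage the channels refer to.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param signal_kind One of `"intensity"`, `"od"`, `"concentration"`.
#' @param chromophore `"HbO"`, `"HbR"` or `NA` (non-concentration data).
#' @param wavelength Wavelength in nm for optical data, `NA` otherwise.
#' @param montage Optional `ot_montage`; channel count must match.
#' @return An object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(data, sampling_rate = 6.78,
                            signal_kind = c("concentration", "intensity", "od"),
                            chromophore = NA_character_,
                            wavelength = NA_real_,
                            montage = NULL) {
  signal_kind <- match.arg(signal_kind)
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be finite numeric")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (!is.null(montage) && nrow(data) != n_channels(montage))
    stop("channel count does not match montage")
  if (is.null(rownames(data)))
    rownames(data) <- paste0("ch", seq_len(nrow(data)))
  structure(list(data = data, sampling_rate = sampling_rate,
                 signal_kind = signal_kind, chromophore = chromophore,
                 wavelength = wavelength, montage = montage),
            class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat("<fnirs_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sampling_rate, " Hz [", x$signal_kind,
      if (!is.na(x$chromophore)) paste0(", ", x$chromophore) else "",
      if (!is.na(x$wavelength)) paste0(", ", x$wavelength, " nm") else "",
      "]\n", sep = "")
  invisible(x)
}

#' Tidy a recording into a long tibble
#'
#' @param x An `fnirs_recording`.
#' @param ... Unused.
#' @return Tibble with `channel`, `time` (s), `value`.
#' @export
tidy.fnirs_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    channel = rep(seq_len(nrow(x$data)), each = n),
    time = rep((seq_len(n) - 1) / x$sampling_rate, nrow(x$data)),
    value = as.vector(t(x$data))
  )
}

# apply a per-channel function (vector -> vector) to every row
map_channels <- function(recording, f, ...) {
  out <- recording
  res <- t(apply(recording$data, 1, f, ...))
  dimnames(res) <- dimnames(recording$data)
  out$data <- res
  out
}

#' Write a recording to the plain-text channel-by-sample CSV format
#'
#' First line is a `#`-prefixed header carrying `sampling_rate`,
#' `signal_kind`, `chromophore` and `wavelength`; the remainder is a CSV
#' with a `channel` column followed by one column per sample.
#'
#' @param recording An `fnirs_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  hdr <- sprintf("# sampling_rate=%.10g signal_kind=%s chromophore=%s wavelength=%s",
                 recording$sampling_rate, recording$signal_kind,
                 recording$chromophore, recording$wavelength)
  df <- data.frame(channel = rownames(recording$data), recording$data,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#'
#' @param path File path.
#' @param montage Optional montage to attach.
#' @return An `fnirs_recording`.
#' @export
read_recording_csv <- function(path, montage = NULL) {
  lines <- readLines(path, n = 1)
  if (!startsWith(lines, "# "))
    stop("missing sampling information header in ", path)
  kv <- strsplit(sub("^# ", "", lines), " ")[[1]]
  meta <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  if (!"sampling_rate" %in% names(meta))
    stop("missing sampling_rate in header of ", path)
  df <- read.csv(path, skip = 1, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$channel, NULL)
  fnirs_recording(
    m, sampling_rate = as.numeric(meta[["sampling_rate"]]),
    signal_kind = meta[["signal_kind"]],
    chromophore = if (meta[["chromophore"]] %in% c("NA", "")) NA_character_ else meta[["chromophore"]],
    wavelength = if (meta[["wavelength"]] %in% c("NA", "")) NA_real_ else as.numeric(meta[["wavelength"]]),
    montage = montage
  )
}
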