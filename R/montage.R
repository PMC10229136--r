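#' Default 26-channel probe montage
#'
#' Builds the probe geometry used throughout the pipeline: a 26-channel
#' array formed by 12 sources and 13 detectors at 3 cm separation, with the
#' channels partitioned into five bilateral regions of interest (ROIs)
#' covering the touch-processing network: posterior superior temporal
#' sulcus (pSTS), primary somatosensory cortex (S1), and lateral, mediolateral
#' and medial orbitofrontal cortex (lOFC, mlOFC, mOFC).
#'
#' The source/detector pairing is a synthetic layout consistent with the
#' channel/optode counts; ROI membership is the part the analysis depends on:
#' pSTS = channels 1-4 and 23-26, S1 = 5-8 and 19-22, lOFC = 9 and 18,
#' mlOFC = 10, 11, 16, 17, mOFC = 12-15.
#'
#' @param source_detector_distance Source-detector separation in cm.
#' @return An object of class `ot_montage`: a list with `channels`
#'   (tibble: `channel`, `source`, `detector`), `roi_map` (named list of
#'   integer channel sets) and `source_detector_distance`.
#' @examples
#' m <- make_montage()
#' m$roi_map$mOFC
#' @export
make_montage <- function(source_detector_distance = 3) {
  channels <- tibble::tibble(
    channel  = 1:26,
    source   = ((1:26 - 1L) %% 12L) + 1L,
    detector = ((1:26 - 1L) %% 13L) + 1L
  )
  roi_map <- list(
    pSTS  = c(1:4, 23:26),
    S1    = c(5:8, 19:22),
    lOFC  = c(9L, 18L),
    mlOFC = c(10L, 11L, 16L, 17L),
    mOFC  = 12:15
  )
  m <- structure(
    list(channels = channels,
         roi_map = lapply(roi_map, as.integer),
         source_detector_distance = source_detector_distance),
    class = "ot_montage"
  )
  validate_montage(m)
  m
}

#' Validate a montage
#'
#' Checks the structural invariants: channel ids unique, ROI map a partition
#' of the channel set (no channel in two ROIs).
#'
#' @param montage An `ot_montage`.
#' @return The montage, invisibly; errors on violation.
#' @export
validate_montage <- function(montage) {
  stopifnot(inherits(montage, "ot_montage"))
  ch <- montage$channels$channel
  if (anyDuplicated(ch)) stop("duplicate channel ids in montage")
  pooled <- unlist(montage$roi_map, use.names = FALSE)
  if (anyDuplicated(pooled)) stop("a channel appears in more than one ROI")
  if (!all(pooled %in% ch)) stop("roi_map refers to unknown channels")
  invisible(montage)
}

#' @export
print.ot_montage <- function(x, ...) {
  cat("<ot_montage> ", nrow(x$channels), " channels, ",
      length(unique(x$channels$source)), " sources, ",
      length(unique(x$channels$detector)), " detectors, ",
      x$source_detector_distance, " cm separation\n", sep = "")
  for (r in names(x$roi_map)) {
    cat("  ", format(r, width = 6), ": ",
        paste(x$roi_map[[r]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

n_channels <- function(montage) nrow(montage$channels)
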