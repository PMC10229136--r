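#' Group-mean block-averaged ROI time courses
#'
#' The descriptive companion of the classifier: per treatment arm and ROI,
#' the block-averaged oxy-Hb curve for one condition, averaged over the
#' analyzed subjects — the kind of display where oxytocin-induced response
#' prolongation shows up as a slower post-offset return to baseline.
#'
#' @param cohort An `ot_cohort` with the `"fnirs"` component.
#' @param rois ROIs to show.
#' @param condition Condition whose blocks are averaged.
#' @param window Window in seconds relative to block onset.
#' @param config A [preprocess_config()].
#' @param stages Preprocessing stages (see [preprocess()]).
#' @return A ggplot (curves facetted by ROI, coloured by arm).
#' @export
plot_roi_timecourses <- function(cohort, rois = c("mOFC", "mlOFC", "pSTS"),
                                 condition = "gentle_touch",
                                 window = c(0, 45),
                                 config = preprocess_config(),
                                 stages = c("detrend", "bandpass")) {
  subj <- analyzed_subjects(cohort)
  design <- if (condition == "gentle_touch") cohort$config$design_touch
  else cohort$config$design_massage
  fs <- design$sampling_rate
  rec_col <- paste0("rec_", condition)
  rows <- purrr::map_dfr(seq_len(nrow(subj)), function(i) {
    ba <- block_average(preprocess(subj[[rec_col]][[i]], config, stages),
                        design, condition, window)
    purrr::map_dfr(rois, function(r) {
      curve <- colMeans(ba[cohort$montage$roi_map[[r]], , drop = FALSE])
      tibble::tibble(group = subj$group[i], roi = r,
                     time = window[1] + (seq_along(curve) - 1) / fs,
                     value = curve)
    })
  })
  mean_curves <- rows |>
    dplyr::group_by(.data$group, .data$roi, .data$time) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  stim_s <- design$events$duration[design$events$condition == condition][1]
  ggplot2::ggplot(mean_curves,
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, stim_s), linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$roi), scales = "free_y") +
    ggplot2::labs(x = "time from block onset (s)",
                  y = "oxy-Hb concentration change (uM)",
                  colour = "arm") +
    ggplot2::theme_minimal()
}
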