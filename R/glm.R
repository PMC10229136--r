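#' Fit the first-level GLM per channel
#'
#' Ordinary least squares of each channel's time series on the design
#' matrix. All-zero columns (conditions absent from the session) are
#' dropped before fitting; remaining rank deficiency is an error naming
#' the offending columns.
#'
#' @param recording A concentration `fnirs_recording`.
#' @param design_matrix A `design_matrix` from [build_design()] with rows
#'   matching the recording's sample count.
#' @return An `fnirs_glm`: list with `betas` (channel x regressor tibble-
#'   backed matrix), `residual_variance` (per channel, RSS/dof), `dof`,
#'   and the design used.
#' @export
fit_glm <- function(recording, design_matrix) {
  X <- design_matrix$values
  Y <- t(recording$data) # samples x channels
  if (nrow(X) != nrow(Y))
    stop("design rows (", nrow(X), ") do not match samples (", nrow(Y), ")")
  keep <- colSums(abs(X)) > 0
  if (any(!keep))
    message("dropping empty regressor(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qrx, Y) # regressors x channels
  R <- Y - X %*% B
  dof <- nrow(X) - ncol(X)
  if (dof <= 0) stop("no residual degrees of freedom")
  betas <- t(B)
  colnames(betas) <- colnames(X)
  rownames(betas) <- rownames(recording$data)
  structure(list(betas = betas,
                 residual_variance = colSums(R^2) / dof,
                 dof = dof,
                 regressors = colnames(X)),
            class = "fnirs_glm")
}

#' @export
print.fnirs_glm <- function(x, ...) {
  cat("<fnirs_glm> ", nrow(x$betas), " channels, regressors: ",
      paste(x$regressors, collapse = ", "), ", dof = ", x$dof, "\n", sep = "")
  invisible(x)
}

#' Tidy GLM betas into a long tibble
#' @param x An `fnirs_glm`.
#' @param ... Unused.
#' @return Tibble with `channel`, `regressor`, `estimate`.
#' @export
tidy.fnirs_glm <- function(x, ...) {
  tibble::tibble(
    channel = rep(seq_len(nrow(x$betas)), times = ncol(x$betas)),
    regressor = rep(colnames(x$betas), each = nrow(x$betas)),
    estimate = as.vector(x$betas)
  )
}

#' Stimulation-minus-rest contrast
#'
#' Per channel, the beta of the stimulation condition minus the beta of its
#' matching rest regressor (`gentle_touch - rest_after_touch`,
#' `medium_massage - rest_after_massage`).
#'
#' @param glm_result An `fnirs_glm`.
#' @param condition `"gentle_touch"` or `"medium_massage"`.
#' @return Named numeric vector, one value per channel.
#' @export
contrast_stim_minus_rest <- function(glm_result,
                                     condition = c("gentle_touch",
                                                   "medium_massage")) {
  condition <- match.arg(condition)
  rest <- REST_OF[[condition]]
  B <- glm_result$betas
  for (col in c(condition, rest)) {
    if (!col %in% colnames(B))
      stop("regressor ", col, " not present in the fitted model")
  }
  B[, condition] - B[, rest]
}

#' Aggregate channel values into ROI means
#'
#' Unweighted mean of the member channels of each ROI in the montage.
#'
#' @param channel_values Numeric vector with one value per montage channel
#'   (in channel order 1..n).
#' @param montage An `ot_montage`.
#' @param label Optional contrast/condition label stored in the output.
#' @return Tibble with `roi`, `value` (and `label` if given).
#' @export
roi_aggregate <- function(channel_values, montage, label = NULL) {
  if (length(channel_values) != n_channels(montage))
    stop("need exactly one value per montage channel")
  out <- tibble::tibble(
    roi = names(montage$roi_map),
    value = unname(vapply(montage$roi_map,
                          function(chs) mean(channel_values[chs]),
                          numeric(1)))
  )
  if (!is.null(label)) out$label <- label
  out
}

#' Per-subject ROI contrast table
#'
#' Convenience wrapper binding [fit_glm()], [contrast_stim_minus_rest()] and
#' [roi_aggregate()]: fits the GLM and returns the ROI-mean
#' stimulation-minus-rest contrast for each requested condition.
#'
#' @param recording A preprocessed concentration `fnirs_recording` with a
#'   montage attached.
#' @param design_matrix The matching `design_matrix`.
#' @param conditions Conditions to contrast.
#' @return Tibble with `condition`, `roi`, `value`.
#' @export
roi_contrast_table <- function(recording, design_matrix,
                               conditions = c("gentle_touch",
                                              "medium_massage")) {
  if (is.null(recording$montage)) stop("recording has no montage")
  fit <- fit_glm(recording, design_matrix)
  purrr::map_dfr(conditions, function(cond) {
    cv <- contrast_stim_minus_rest(fit, cond)
    out <- roi_aggregate(cv, recording$montage)
    out$condition <- cond
    out[, c("condition", "roi", "value")]
  })
}
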