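#' Block-averaged time course
#'
#' Averages, per channel, the windowed segments locked to every block of
#' the given condition: window `(w0, w1)` seconds relative to block onset.
#' Segment length is `floor((w1 - w0) * sampling_rate)` samples.
#'
#' @param recording An `fnirs_recording`.
#' @param design The matching `block_design`.
#' @param condition Condition whose blocks to average.
#' @param window Numeric `(start, end)` in seconds relative to onset
#'   (default `c(5, 35)`).
#' @param baseline_correct If `TRUE`, subtract each block's mean over the
#'   0 to `window[1]` pre-window before averaging (off by default).
#' @return Matrix channels x window samples.
#' @export
block_average <- function(recording, design, condition, window = c(5, 35),
                          baseline_correct = FALSE) {
  fs <- recording$sampling_rate
  len <- floor((window[2] - window[1]) * fs)
  ev <- design$events[design$events$condition == condition, ]
  if (nrow(ev) == 0) stop("no blocks of condition ", condition)
  n <- ncol(recording$data)
  acc <- matrix(0, nrow(recording$data), len)
  for (i in seq_len(nrow(ev))) {
    i0 <- round((ev$onset[i] + window[1]) * fs) + 1
    if (i0 < 1 || i0 + len - 1 > n)
      stop("window for block at ", ev$onset[i], " s exceeds recording bounds")
    seg <- recording$data[, i0:(i0 + len - 1), drop = FALSE]
    if (baseline_correct) {
      b0 <- round(ev$onset[i] * fs) + 1
      base <- rowMeans(recording$data[, b0:(i0 - 1), drop = FALSE])
      seg <- seg - base
    }
    acc <- acc + seg
  }
  out <- acc / nrow(ev)
  rownames(out) <- rownames(recording$data)
  out
}

#' Extract a subject's classification feature vector
#'
#' Per requested ROI, the member channels of the block-averaged curve are
#' averaged and the per-ROI curves concatenated in the order given
#' (default mOFC, mlOFC, pSTS) — the pattern used for group decoding.
#'
#' @param recording A preprocessed concentration `fnirs_recording`.
#' @param design The matching `block_design`.
#' @param montage An `ot_montage` (defaults to the recording's).
#' @param rois ROIs to include, in concatenation order.
#' @param condition Condition whose blocks are averaged.
#' @param window Feature window in seconds relative to onset.
#' @param baseline_correct See [block_average()].
#' @return Numeric feature vector of length
#'   `length(rois) * floor(diff(window) * sampling_rate)`.
#' @export
extract_features <- function(recording, design, montage = recording$montage,
                             rois = c("mOFC", "mlOFC", "pSTS"),
                             condition = "gentle_touch",
                             window = c(5, 35),
                             baseline_correct = FALSE) {
  if (is.null(montage)) stop("no montage available")
  bad <- setdiff(rois, names(montage$roi_map))
  if (length(bad) > 0) stop("unknown ROI: ", paste(bad, collapse = ", "))
  ba <- block_average(recording, design, condition, window, baseline_correct)
  unlist(lapply(rois, function(r) {
    colMeans(ba[montage$roi_map[[r]], , drop = FALSE])
  }), use.names = FALSE)
}

# Gram-matrix core: leave-one-out nearest-group-mean classification.
# G = F F', s = rowSums(F), q = diag(G), p = feature length.
# Returns list(accuracy, predicted, n_ties, n_undefined).
loo_core <- function(G, s, q, p, labels, similarity = "pearson") {
  lev <- sort(unique(labels))
  stopifnot(length(lev) == 2)
  n <- length(labels)
  ind <- cbind(labels == lev[1], labels == lev[2])
  ng <- colSums(ind)
  R <- G %*% ind                      # R[i,g] = sum_j in g G[i,j]
  Sg <- colSums(ind * s)              # total feature sums per group
  Qg <- colSums(R * ind)              # sum of G over group block
  sims <- matrix(NA_real_, n, 2)
  for (g in 1:2) {
    member <- ind[, g]
    ngm <- ng[g] - 1
    # member subjects: mean excludes self
    sxm <- ifelse(member, (R[, g] - q) / ngm, R[, g] / ng[g])
    sm <- ifelse(member, (Sg[g] - s) / ngm, Sg[g] / ng[g])
    smm <- ifelse(member,
                  (Qg[g] - 2 * R[, g] + q) / ngm^2,
                  Qg[g] / ng[g]^2)
    if (similarity == "pearson") {
      num <- p * sxm - s * sm
      den <- sqrt(pmax(p * q - s^2, 0) * pmax(p * smm - sm^2, 0))
      sims[, g] <- ifelse(den > 0, num / den, NA_real_)
    } else { # cosine
      den <- sqrt(q * smm)
      sims[, g] <- ifelse(den > 0, sxm / den, NA_real_)
    }
  }
  undef <- !is.finite(sims[, 1]) | !is.finite(sims[, 2])
  tie <- !undef & sims[, 1] == sims[, 2]
  pred <- ifelse(undef | tie, NA_character_,
                 ifelse(sims[, 1] > sims[, 2], lev[1], lev[2]))
  correct <- !is.na(pred) & pred == labels
  list(accuracy = mean(correct), predicted = pred,
       n_ties = sum(tie), n_undefined = sum(undef))
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    stop("pass features as a numeric matrix (subjects x features); ",
         "see cohort_feature_matrix()")
  }
  as.matrix(features)
}

#' Leave-one-out nearest-group-mean classification
#'
#' Each subject's feature vector is compared (default: Pearson
#' correlation) with the mean feature vector of each of the two groups,
#' the subject's own group mean computed without that subject; the more
#' similar group is predicted. Exact similarity ties and subjects with
#' undefined similarity (constant feature vector) are counted as
#' incorrect and tallied.
#'
#' @param features Numeric matrix, subjects x features.
#' @param labels Group label per subject (exactly 2 distinct values,
#'   >= 2 subjects each).
#' @param similarity `"pearson"` (default) or `"cosine"`.
#' @return An `ot_classification`: accuracy, per-subject `predictions`
#'   tibble, tie/undefined counts; `null_distribution` and `p_value` are
#'   `NULL` until [permutation_test()] fills them.
#' @export
loo_classify <- function(features, labels,
                         similarity = c("pearson", "cosine")) {
  similarity <- match.arg(similarity)
  F <- feature_matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2)
    stop("need exactly 2 distinct labels")
  if (min(table(labels)) < 2) stop("need >= 2 subjects per label")
  if (nrow(F) != length(labels)) stop("features/labels length mismatch")
  G <- tcrossprod(F)
  res <- loo_core(G, rowSums(F), diag(G), ncol(F), labels, similarity)
  structure(list(
    accuracy = res$accuracy,
    predictions = tibble::tibble(
      subject = rownames(F) %||% as.character(seq_len(nrow(F))),
      truth = labels, predicted = res$predicted,
      correct = !is.na(res$predicted) & res$predicted == labels),
    n_ties = res$n_ties, n_undefined = res$n_undefined,
    similarity = similarity,
    null_distribution = NULL, p_value = NULL,
    n_permutations = 0L, seed = NA_integer_),
    class = "ot_classification")
}

#' Permutation significance test for the leave-one-out classifier
#'
#' Repeats [loo_classify()] with the treatment labels randomly shuffled
#' `n_permutations` times; the p value is the literal proportion of null
#' accuracies greater than or equal to the actual accuracy. With
#' `add_one = TRUE` the conventional `(b + 1) / (m + 1)` estimator is used
#' instead (off by default).
#'
#' @inheritParams loo_classify
#' @param n_permutations Number of label shuffles (default 10000).
#' @param seed Integer seed.
#' @param add_one Use the `(b+1)/(m+1)` p estimator.
#' @return A complete `ot_classification` with `null_distribution` and
#'   `p_value`.
#' @export
permutation_test <- function(features, labels, n_permutations = 10000,
                             seed = 1,
                             similarity = c("pearson", "cosine"),
                             add_one = FALSE) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  similarity <- match.arg(similarity)
  res <- loo_classify(features, labels, similarity)
  F <- feature_matrix(features)
  labels <- as.character(labels)
  G <- tcrossprod(F)
  s <- rowSums(F); q <- diag(G); p <- ncol(F)
  null_acc <- withr_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      loo_core(G, s, q, p, sample(labels), similarity)$accuracy
    }, numeric(1))
  })
  b <- sum(null_acc >= res$accuracy)
  res$null_distribution <- null_acc
  res$p_value <- if (add_one) (b + 1) / (n_permutations + 1)
  else b / n_permutations
  res$n_permutations <- as.integer(n_permutations)
  res$seed <- seed
  res
}

#' @export
print.ot_classification <- function(x, ...) {
  cat("<ot_classification> accuracy ", sprintf("%.3f", x$accuracy),
      " (", sum(x$predictions$correct), "/", nrow(x$predictions), ")",
      if (x$n_ties > 0) paste0(", ", x$n_ties, " ties"), sep = "")
  if (!is.null(x$p_value))
    cat(", permutation p = ", format(x$p_value, digits = 3),
        " (", x$n_permutations, " permutations)", sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy per-subject classification predictions
#' @param x An `ot_classification`.
#' @param ... Unused.
#' @return The predictions tibble.
#' @export
tidy.ot_classification <- function(x, ...) x$predictions

#' One-row classification summary
#' @param x An `ot_classification`.
#' @param ... Unused.
#' @return Tibble with accuracy, tie/undefined counts, permutation p.
#' @export
glance.ot_classification <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = nrow(x$predictions),
                 n_ties = x$n_ties, n_undefined = x$n_undefined,
                 n_permutations = x$n_permutations,
                 p_value = x$p_value %||% NA_real_)
}

#' Plot the permutation null distribution with the observed accuracy
#' @param object An `ot_classification` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ot_classification <- function(object, ...) {
  if (is.null(object$null_distribution))
    stop("no null distribution; run permutation_test()")
  df <- tibble::tibble(accuracy = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$accuracy, colour = "red") +
    ggplot2::labs(
      x = "null accuracy", y = "count",
      title = sprintf("observed accuracy %.3f, p = %s",
                      object$accuracy, format(object$p_value, digits = 3))) +
    ggplot2::theme_minimal()
}

#' Feature matrix for an entire cohort
#'
#' Runs preprocessing and [extract_features()] over the analyzed subjects
#' of two treatment arms and stacks the vectors into the matrix
#' [loo_classify()] consumes.
#'
#' @param cohort An `ot_cohort` generated with the `"fnirs"` component.
#' @param groups Two arms to contrast.
#' @param config A [preprocess_config()].
#' @param stages Preprocessing stages to run (see [preprocess()]).
#' @param rois,window,condition,baseline_correct Passed to
#'   [extract_features()].
#' @return List with `features` (matrix, rownames = subject ids) and
#'   `labels`.
#' @export
cohort_feature_matrix <- function(cohort,
                                  groups = c("intranasal_OT", "PLC"),
                                  config = preprocess_config(),
                                  stages = c("detrend", "bandpass"),
                                  rois = c("mOFC", "mlOFC", "pSTS"),
                                  window = c(5, 35),
                                  condition = "gentle_touch",
                                  baseline_correct = FALSE) {
  subj <- analyzed_subjects(cohort) |>
    dplyr::filter(.data$group %in% groups)
  rec_col <- paste0("rec_", condition)
  design <- if (condition == "gentle_touch") cohort$config$design_touch
  else cohort$config$design_massage
  # preprocess only the channels the requested ROIs use: every stage is
  # channel-wise, so restriction commutes with preprocessing
  montage <- cohort$montage
  needed <- sort(unique(unlist(montage$roi_map[rois])))
  sub_montage <- montage
  sub_montage$channels <- montage$channels[needed, ]
  sub_montage$roi_map <- lapply(montage$roi_map[rois],
                                function(chs) match(chs, needed))
  feats <- lapply(subj[[rec_col]], function(rec) {
    sub <- rec
    sub$data <- rec$data[needed, , drop = FALSE]
    sub$montage <- sub_montage
    extract_features(preprocess(sub, config, stages), design,
                     montage = sub_montage, rois = rois,
                     condition = condition, window = window,
                     baseline_correct = baseline_correct)
  })
  F <- do.call(rbind, feats)
  rownames(F) <- subj$id
  list(features = F, labels = subj$group)
}
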