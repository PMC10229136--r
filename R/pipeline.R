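#' Pipeline configuration
#'
#' Bundles every stage's parameters with the study defaults: 20 blocks of
#' 30 s + 15 s rest at 6.78 Hz, 0.01-0.08 Hz bandpass, 5-35 s feature
#' window, 10000 permutations, 5000 bootstraps.
#'
#' @param cohort A [cohort_config()].
#' @param preprocess A [preprocess_config()].
#' @param preprocess_stages Stages [preprocess()] runs.
#' @param hrf_params See [canonical_hrf()].
#' @param classify_groups Two arms the classifier contrasts.
#' @param classify_rois ROIs entering the feature vector.
#' @param classify_window Feature window, seconds.
#' @param n_permutations Label permutations for significance.
#' @param similarity Classifier similarity metric.
#' @param n_boot Mediation bootstrap resamples.
#' @param mediation_routes Routes to run mediation for.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            preprocess = preprocess_config(),
                            preprocess_stages = c("detrend", "tddr",
                                                  "bandpass"),
                            hrf_params = default_hrf_params(),
                            classify_groups = c("intranasal_OT", "PLC"),
                            classify_rois = c("mOFC", "mlOFC", "pSTS"),
                            classify_window = c(5, 35),
                            n_permutations = 10000,
                            similarity = "pearson",
                            n_boot = 5000,
                            mediation_routes = c("intranasal_OT", "oral_OT"),
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

# flatten a config into YAML-serializable plain lists
config_to_list <- function(x) {
  strip <- function(v) {
    if (inherits(v, "block_design"))
      return(list(events = as.data.frame(v$events),
                  sampling_rate = v$sampling_rate))
    if (is.data.frame(v)) return(as.data.frame(v))
    if (is.matrix(v)) return(list(.matrix = as.vector(v), .dim = dim(v),
                                  .dimnames = dimnames(v)))
    if (is.list(v)) return(lapply(v, strip))
    if (is.atomic(v) && !is.null(names(v))) return(as.list(v))
    v
  }
  lapply(unclass(x), strip)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild <- function(v) {
    if (is.list(v) && !is.null(v$.matrix))
      return(matrix(unlist(v$.matrix), nrow = v$.dim[[1]],
                    dimnames = v$.dimnames))
    if (is.list(v) && !is.null(v$events) && !is.null(v$sampling_rate))
      return(structure(list(events = tibble::as_tibble(
        as.data.frame(lapply(v$events, unlist))),
        sampling_rate = v$sampling_rate), class = "block_design"))
    if (is.list(v)) return(lapply(v, rebuild))
    v
  }
  out <- lapply(raw, rebuild)
  # restore atomic-vector fields YAML stored as lists
  vecify <- function(x) if (is.list(x)) unlist(x) else x
  for (nm in c("preprocess_stages", "classify_groups", "classify_rois",
               "classify_window", "mediation_routes"))
    out[[nm]] <- vecify(out[[nm]])
  for (nm in c("group_sizes", "components"))
    out$cohort[[nm]] <- vecify(out$cohort[[nm]])
  for (nm in c("wavelengths", "dpf", "band"))
    out$preprocess[[nm]] <- vecify(out$preprocess[[nm]])
  out$hrf_params <- lapply(out$hrf_params, vecify)
  # restore data frames that YAML stored as column lists
  for (nm in c("amplitude", "prolongation", "physio")) {
    if (!is.null(out$cohort$effect[[nm]]))
      out$cohort$effect[[nm]] <- tibble::as_tibble(
        lapply(out$cohort$effect[[nm]], unlist))
  }
  out$cohort$effect <- structure(out$cohort$effect, class = "effect_spec")
  out$cohort <- structure(out$cohort, class = "cohort_config")
  out$preprocess <- structure(out$preprocess, class = "preprocess_config")
  structure(out, class = "pipeline_config")
}

#' Write cohort tables to tidy CSV files
#'
#' Emits `ratings.csv` (subject, group, condition, scale, rating),
#' `plasma.csv` (subject, group, timepoint, pg_ml), `rr.csv` (subject,
#' interval_ms in beat order) and `scr.csv` (subject, condition, time_s,
#' microsiemens), plus a `cohort.yaml` sidecar echoing generator
#' parameters and seed.
#'
#' @param cohort An `ot_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort_ratings(cohort), file.path(dir, "ratings.csv"),
            row.names = FALSE)
  write.csv(cohort_plasma(cohort), file.path(dir, "plasma.csv"),
            row.names = FALSE)
  subj <- analyzed_subjects(cohort)
  if ("rr" %in% names(subj)) {
    rr_tab <- purrr::map_dfr(seq_len(nrow(subj)), function(i) {
      if (is.null(subj$rr[[i]])) return(NULL)
      tibble::tibble(subject = subj$id[i], beat = seq_along(subj$rr[[i]]$rr),
                     interval_ms = subj$rr[[i]]$rr)
    })
    write.csv(rr_tab, file.path(dir, "rr.csv"), row.names = FALSE)
    scr_tab <- purrr::map_dfr(seq_len(nrow(subj)), function(i) {
      purrr::map_dfr(c("gentle_touch", "medium_massage"), function(cond) {
        tr <- subj[[paste0("scr_", cond)]][[i]]
        if (is.null(tr)) return(NULL)
        tibble::tibble(subject = subj$id[i], condition = cond,
                       time_s = (seq_along(tr$samples) - 1) / tr$sampling_rate,
                       microsiemens = tr$samples)
      })
    })
    write.csv(scr_tab, file.path(dir, "scr.csv"), row.names = FALSE)
  }
  yaml::write_yaml(
    list(seed = cohort$seed,
         group_sizes = as.list(cohort$config$group_sizes),
         n_incomplete = cohort$config$n_incomplete,
         n_technical = cohort$config$n_technical),
    file.path(dir, "cohort.yaml"))
  invisible(dir)
}

stage_done <- function(paths) all(file.exists(paths))

#' Run the end-to-end analysis pipeline
#'
#' simulate -> preprocess/GLM/ROI -> classification -> mediation ->
#' autonomic indices -> group statistics, writing every intermediate
#' artifact under `out_dir` and returning a run manifest. With
#' `resume = TRUE`, stages whose declared outputs already exist are
#' skipped.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param resume Skip stages whose outputs exist.
#' @param quiet Suppress stage messages.
#' @return A `run_manifest` list: config echo, seed, per-stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         resume = FALSE, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[oxtouch] ", ...)
  manifest <- list(seed = config$seed, stages = list(),
                   started = format(Sys.time(), tz = "UTC"))

  # --- simulate ----------------------------------------------------------
  cohort_files <- file.path(out_dir, c("ratings.csv", "plasma.csv",
                                       "cohort.yaml"))
  say("simulate: cohort (seed ", config$seed, ")")
  cohort <- simulate_cohort(config$cohort, seed = config$seed)
  if (!(resume && stage_done(cohort_files)))
    write_cohort_csv(cohort, out_dir)
  manifest$stages$simulate <- list(outputs = cohort_files)

  # --- preprocess + GLM + ROI -------------------------------------------
  roi_path <- file.path(out_dir, "roi_contrasts.csv")
  do_fnirs <- "fnirs" %in% config$cohort$components
  if (do_fnirs && !(resume && stage_done(roi_path))) {
    say("glm: per-subject ROI contrasts")
    subj <- analyzed_subjects(cohort)
    full_design <- concat_designs(config$cohort$design_touch,
                                  config$cohort$design_massage)
    X <- build_design(full_design, hrf_params = config$hrf_params)
    roi_tab <- purrr::map_dfr(seq_len(nrow(subj)), function(i) {
      rec_t <- preprocess(subj$rec_gentle_touch[[i]], config$preprocess,
                          config$preprocess_stages)
      rec_m <- preprocess(subj$rec_medium_massage[[i]], config$preprocess,
                          config$preprocess_stages)
      rec <- rec_t
      rec$data <- cbind(rec_t$data, rec_m$data)
      out <- roi_contrast_table(rec, X)
      out$subject <- subj$id[i]
      out$group <- subj$group[i]
      out[, c("subject", "group", "condition", "roi", "value")]
    })
    write.csv(roi_tab, roi_path, row.names = FALSE)
  }
  if (do_fnirs) manifest$stages$glm <- list(outputs = roi_path)

  # --- classification ----------------------------------------------------
  cls_path <- file.path(out_dir, "classification.json")
  if (do_fnirs && !(resume && stage_done(cls_path))) {
    say("classify: ", paste(config$classify_groups, collapse = " vs "))
    fm <- cohort_feature_matrix(
      cohort, groups = config$classify_groups, config = config$preprocess,
      stages = config$preprocess_stages,
      rois = config$classify_rois, window = config$classify_window)
    cls <- permutation_test(fm$features, fm$labels,
                            n_permutations = config$n_permutations,
                            seed = config$seed,
                            similarity = config$similarity)
    jsonlite::write_json(
      list(groups = config$classify_groups,
           accuracy = cls$accuracy, p_value = cls$p_value,
           n_permutations = cls$n_permutations, seed = cls$seed,
           n_ties = cls$n_ties,
           null_summary = list(mean = mean(cls$null_distribution),
                               q95 = unname(quantile(cls$null_distribution,
                                                     0.95)))),
      cls_path, auto_unbox = TRUE, digits = NA)
  }
  if (do_fnirs) manifest$stages$classify <- list(outputs = cls_path)

  # --- mediation ---------------------------------------------------------
  med_paths <- file.path(out_dir, paste0("mediation_",
                                         config$mediation_routes, ".json"))
  if (!(resume && stage_done(med_paths))) {
    for (i in seq_along(config$mediation_routes)) {
      route <- config$mediation_routes[i]
      say("mediate: ", route, " vs PLC")
      md <- cohort_mediation_table(cohort, route)
      fit <- mediate(md, x, m, y, n_boot = config$n_boot, seed = config$seed)
      jsonlite::write_json(
        list(route = route, a = fit$a, b = fit$b, c = fit$c,
             c_prime = fit$c_prime, indirect = fit$indirect,
             se_boot = fit$se_boot, ci_95 = fit$ci_95,
             n_boot = fit$n_boot, seed = fit$seed, n = fit$n),
        med_paths[i], auto_unbox = TRUE, digits = NA)
    }
  }
  manifest$stages$mediate <- list(outputs = med_paths)

  # --- autonomic ---------------------------------------------------------
  auto_path <- file.path(out_dir, "autonomic.csv")
  do_auto <- "autonomic" %in% config$cohort$components
  if (do_auto && !(resume && stage_done(auto_path))) {
    say("autonomic: indices")
    subj <- analyzed_subjects(cohort)
    designs <- list(gentle_touch = config$cohort$design_touch,
                    medium_massage = config$cohort$design_massage)
    auto_tab <- purrr::map_dfr(seq_len(nrow(subj)), function(i) {
      out <- autonomic_indices(
        subj$rr[[i]],
        list(gentle_touch = subj$scr_gentle_touch[[i]],
             medium_massage = subj$scr_medium_massage[[i]]),
        designs)
      out$subject <- subj$id[i]
      out$group <- subj$group[i]
      out
    })
    write.csv(auto_tab, auto_path, row.names = FALSE)
  }
  if (do_auto) manifest$stages$autonomic <- list(outputs = auto_path)

  # --- group statistics --------------------------------------------------
  stats_path <- file.path(out_dir, "anova.csv")
  if (!(resume && stage_done(stats_path))) {
    say("stats: plasma change + pleasantness ANOVAs")
    subj <- analyzed_subjects(cohort)
    plasma_anova <- one_way_anova(
      dplyr::mutate(subj, change = .data$plasma_post_treatment -
                      .data$plasma_baseline),
      change, group) |>
      dplyr::mutate(analysis = "plasma_change", .before = 1)
    long <- cohort_ratings(cohort) |>
      dplyr::filter(.data$scale == "pleasantness")
    pleas_anova <- mixed_anova(long, rating, group, within = "condition",
                               subject = "subject") |>
      dplyr::mutate(analysis = "pleasantness", .before = 1)
    write.csv(dplyr::bind_rows(plasma_anova, pleas_anova), stats_path,
              row.names = FALSE)
  }
  manifest$stages$stats <- list(outputs = stats_path)

  manifest$finished <- format(Sys.time(), tz = "UTC")
  manifest$config <- config_to_list(config)
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
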