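#' Effect specification for the fNIRS forward model
#'
#' Describes what the synthetic recordings contain: per-(ROI, condition)
#' response amplitudes in uM; per-(ROI, condition, group) exponential
#' response prolongation time constants in seconds (the neural drive decays
#' as `exp(-t/tau)` past block offset instead of stopping); per-sample
#' Gaussian noise; sinusoidal physiological components (cardiac,
#' respiratory, Mayer waves) with channel-random phases; and a motion
#' artifact model of isolated spikes and baseline steps.
#'
#' Defaults emulate the study conditions this pipeline targets: gentle
#' stroking touch drives orbitofrontal and pSTS regions most strongly,
#' medium pressure massage drives S1; oxytocin (intranasal or oral)
#' prolongs the gentle-touch response in mOFC, mlOFC and pSTS by
#' `tau = 8 s` relative to placebo.
#'
#' @param amplitude Tibble (`roi`, `condition`, `amplitude`), uM.
#' @param prolongation Tibble (`roi`, `condition`, `group`, `tau`), seconds.
#' @param noise_sd Per-sample Gaussian noise SD, uM.
#' @param physio Tibble (`label`, `freq`, `amp`): sinusoidal components
#'   (Hz, uM).
#' @param artifact_rate Expected motion artifacts per minute (half spikes,
#'   half baseline steps).
#' @param spike_amp,step_amp Artifact magnitudes, uM.
#' @param subject_amp_sd SD of the per-subject multiplicative amplitude
#'   jitter (1 + N(0, sd)).
#' @param subject_tau_sd SD of per-subject additive jitter on tau, seconds
#'   (floored at 0).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(amplitude = default_amplitudes(),
                        prolongation = default_prolongation(),
                        noise_sd = 0.4,
                        physio = default_physio(),
                        artifact_rate = 0.2,
                        spike_amp = 3,
                        step_amp = 1,
                        subject_amp_sd = 0.2,
                        subject_tau_sd = 2) {
  stopifnot(all(is.finite(amplitude$amplitude)),
            all(prolongation$tau >= 0), noise_sd >= 0)
  structure(list(amplitude = amplitude, prolongation = prolongation,
                 noise_sd = noise_sd, physio = physio,
                 artifact_rate = artifact_rate, spike_amp = spike_amp,
                 step_amp = step_amp, subject_amp_sd = subject_amp_sd,
                 subject_tau_sd = subject_tau_sd),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
default_amplitudes <- function() {
  tibble::tibble(
    roi = rep(c("pSTS", "S1", "lOFC", "mlOFC", "mOFC"), 2),
    condition = rep(c("gentle_touch", "medium_massage"), each = 5),
    amplitude = c(0.5, 0.4, 0.3, 0.6, 0.6,
                  0.3, 0.6, 0.3, 0.3, 0.3)
  )
}

#' @rdname effect_spec
#' @export
default_prolongation <- function() {
  tidyr::expand_grid(
    roi = c("mOFC", "mlOFC", "pSTS"),
    condition = "gentle_touch",
    group = c("intranasal_OT", "oral_OT")
  ) |>
    dplyr::mutate(tau = 8)
}

#' @rdname effect_spec
#' @export
default_physio <- function() {
  tibble::tibble(label = c("cardiac", "respiratory", "mayer"),
                 freq = c(1.1, 0.25, 0.10),
                 amp = c(0.2, 0.1, 0.1))
}

#' A null effect specification (no signal, no noise, no physiology)
#' @return An `effect_spec` producing all-zero recordings.
#' @export
null_effect_spec <- function() {
  effect_spec(
    amplitude = dplyr::mutate(default_amplitudes(), amplitude = 0),
    prolongation = dplyr::mutate(default_prolongation(), tau = 0),
    noise_sd = 0,
    physio = dplyr::mutate(default_physio(), amp = 0),
    artifact_rate = 0, subject_amp_sd = 0, subject_tau_sd = 0
  )
}

spec_amplitude <- function(spec, roi, condition) {
  a <- spec$amplitude
  hit <- a$roi == roi & a$condition == condition
  if (!any(hit)) 0 else a$amplitude[which(hit)[1]]
}

spec_tau <- function(spec, roi, condition, group) {
  p <- spec$prolongation
  if (nrow(p) == 0) return(0)
  hit <- p$roi == roi & p$condition == condition & p$group == group
  if (!any(hit)) 0 else p$tau[which(hit)[1]]
}

#' Simulate one subject's fNIRS recording
#'
#' Forward model: for every ROI, the neural drive of each condition (boxcar
#' with exponential post-offset tail of the group's time constant) is
#' convolved with the canonical HRF and scaled by the (ROI, condition)
#' amplitude times the subject's amplitude jitter; channel signals add
#' Gaussian noise, physiological sinusoids with random phase, and optional
#' spike/step motion artifacts. Identical `(inputs, seed)` give an
#' identical recording.
#'
#' @param montage An `ot_montage`.
#' @param design A `block_design` (single- or multi-condition).
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @param group Treatment arm, selects prolongation taus.
#' @param hrf_params HRF parameters for the forward model.
#' @return A concentration `fnirs_recording` (HbO, uM).
#' @export
simulate_subject_fnirs <- function(montage, design, spec = effect_spec(),
                                   seed = 1, group = "PLC",
                                   hrf_params = default_hrf_params()) {
  validate_montage(montage)
  bad_roi <- setdiff(unique(c(spec$amplitude$roi, spec$prolongation$roi)),
                     names(montage$roi_map))
  if (length(bad_roi) > 0)
    stop("unknown ROI in effect_spec: ", paste(bad_roi, collapse = ", "))
  n <- design_n_samples(design)
  fs <- design$sampling_rate
  conds <- intersect(unique(design$events$condition), OT_CONDITIONS)
  n_ch <- n_channels(montage)
  withr_seed(seed, {
    amp_jit <- 1 + rnorm(1, 0, spec$subject_amp_sd)
    tau_jit <- rnorm(1, 0, spec$subject_tau_sd)
    data <- matrix(0, n_ch, n,
                   dimnames = list(paste0("ch", montage$channels$channel),
                                   NULL))
    # cache HRF-convolved drives per (condition, tau): ROIs sharing a time
    # constant share the expensive convolution
    conv_cache <- new.env(parent = emptyenv())
    conv_for <- function(cond, tau) {
      key <- paste(cond, signif(tau, 10))
      if (is.null(conv_cache[[key]]))
        conv_cache[[key]] <- convolve_hrf(condition_drive(design, cond, tau),
                                          fs, hrf_params)
      conv_cache[[key]]
    }
    for (roi in names(montage$roi_map)) {
      sig <- numeric(n)
      for (cond in conds) {
        a <- spec_amplitude(spec, roi, cond) * amp_jit
        if (a == 0) next
        tau0 <- spec_tau(spec, roi, cond, group)
        tau <- if (tau0 > 0) max(0, tau0 + tau_jit) else 0
        sig <- sig + a * conv_for(cond, tau)
      }
      data[montage$roi_map[[roi]], ] <-
        matrix(sig, length(montage$roi_map[[roi]]), n, byrow = TRUE)
    }
    if (nrow(spec$physio) > 0 && any(spec$physio$amp > 0)) {
      tvec <- (seq_len(n) - 1) / fs
      for (i in seq_len(nrow(spec$physio))) {
        if (spec$physio$amp[i] <= 0) next
        ph <- runif(n_ch, 0, 2 * pi) # independent phase per channel
        data <- data + spec$physio$amp[i] *
          sin(outer(ph, 2 * pi * spec$physio$freq[i] * tvec, "+"))
      }
    }
    if (spec$noise_sd > 0)
      data <- data + matrix(rnorm(n_ch * n, 0, spec$noise_sd), n_ch, n)
    if (spec$artifact_rate > 0) {
      for (ch in seq_len(n_ch)) {
        n_art <- rpois(1, spec$artifact_rate * design_duration(design) / 60)
        if (n_art == 0) next
        at <- sample.int(n, n_art)
        kind <- runif(n_art) < 0.5
        for (j in seq_len(n_art)) {
          if (kind[j]) {
            data[ch, at[j]] <- data[ch, at[j]] +
              sample(c(-1, 1), 1) * spec$spike_amp
          } else {
            shift <- sample(c(-1, 1), 1) * spec$step_amp
            data[ch, at[j]:n] <- data[ch, at[j]:n] + shift
          }
        }
      }
    }
    fnirs_recording(data, fs, "concentration", chromophore = "HbO",
                    montage = montage)
  })
}

#' Simulate an RR-interval series
#'
#' Beat-to-beat intervals around `60000 / mean_hr_bpm` ms, modulated
#' sinusoidally at a low-frequency (default 0.1 Hz, Mayer-band) and a
#' high-frequency (respiratory) component, plus white jitter. Modulation is
#' evaluated at each beat's cumulative occurrence time.
#'
#' @param duration_s Total duration to cover, seconds.
#' @param mean_hr_bpm Mean heart rate, beats/min, in (30, 200).
#' @param lf_amp,hf_amp Modulation amplitudes, ms.
#' @param hf_freq High-frequency modulation frequency, Hz (default 0.25).
#' @param lf_freq Low-frequency modulation frequency, Hz (default 0.10).
#' @param jitter_sd White jitter SD, ms.
#' @param seed Integer seed.
#' @return An `rr_series`: list with `rr` (ms).
#' @export
simulate_rr <- function(duration_s, mean_hr_bpm = 70, lf_amp = 20,
                        hf_amp = 15, hf_freq = 0.25, lf_freq = 0.10,
                        jitter_sd = 5, seed = 1) {
  if (duration_s <= 0) stop("duration must be > 0")
  if (mean_hr_bpm <= 30 || mean_hr_bpm >= 200)
    stop("mean heart rate outside (30, 200) bpm")
  base <- 60000 / mean_hr_bpm
  withr_seed(seed, {
    t_ms <- 0
    rr <- numeric(0)
    while (t_ms < duration_s * 1000) {
      t_s <- t_ms / 1000
      iv <- base + lf_amp * sin(2 * pi * lf_freq * t_s) +
        hf_amp * sin(2 * pi * hf_freq * t_s) +
        (if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0)
      iv <- min(max(iv, 250), 2500)
      rr <- c(rr, iv)
      t_ms <- t_ms + iv
    }
    rr_series(rr)
  })
}

#' RR-interval series container
#' @param rr Ordered beat-to-beat intervals in ms (250-2500, length >= 2).
#' @return An `rr_series`.
#' @export
rr_series <- function(rr) {
  if (length(rr) < 2) stop("rr series needs at least 2 intervals")
  if (any(rr < 250 | rr > 2500))
    stop("rr intervals outside physiological range (250-2500 ms)")
  structure(list(rr = as.numeric(rr)), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat("<rr_series> ", length(x$rr), " beats, ",
      round(sum(x$rr) / 1000, 1), " s\n", sep = "")
  invisible(x)
}

# canonical skin-conductance response kernel: fast rise, slow decay,
# peak-normalized (peak at ~2.4 s with the default time constants)
scr_kernel <- function(fs, rise = 0.75, decay = 4, len_s = 20) {
  t <- seq(0, len_s, by = 1 / fs)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

#' Simulate a skin-conductance trace for a block design
#'
#' Tonic level plus one phasic response (fast-rise / slow-decay kernel,
#' peak-normalized so `event_amplitude` is the base-to-peak amplitude in
#' uS) at every stimulation-block onset, plus Gaussian noise.
#'
#' @param design A `block_design`.
#' @param event_amplitude Phasic amplitude per event, uS (>= 0).
#' @param tonic Tonic conductance level, uS.
#' @param noise_sd Additive noise SD, uS.
#' @param sampling_rate Trace sampling rate, Hz (default 10; SCR needs no
#'   more).
#' @param seed Integer seed.
#' @return An `scr_trace`: list with `samples` (uS) and `sampling_rate`.
#' @export
simulate_scr <- function(design, event_amplitude = 0.3, tonic = 2,
                         noise_sd = 0.01, sampling_rate = 10, seed = 1) {
  if (event_amplitude < 0) stop("event_amplitude must be >= 0")
  dur <- design_duration(design)
  n <- floor(dur * sampling_rate)
  onsets <- design$events$onset[design$events$condition %in% OT_CONDITIONS]
  kern <- scr_kernel(sampling_rate)
  withr_seed(seed, {
    x <- rep(tonic, n)
    for (on in onsets) {
      i0 <- floor(on * sampling_rate) + 1
      idx <- i0:min(n, i0 + length(kern) - 1)
      x[idx] <- x[idx] + event_amplitude * kern[seq_along(idx)]
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    scr_trace(x, sampling_rate)
  })
}

#' Skin-conductance trace container
#' @param samples Conductance samples in uS (finite).
#' @param sampling_rate Sampling rate, Hz (> 0).
#' @return An `scr_trace`.
#' @export
scr_trace <- function(samples, sampling_rate) {
  if (!all(is.finite(samples))) stop("non-finite SCR samples")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate),
            class = "scr_trace")
}

#' Simulate mediation-structured data for one treatment route
#'
#' The generating model behind the cohort's plasma / pleasantness link:
#' `M = a*X + e_M`, `Y = y0 + c'*X + b*M + e_Y`, with `X` a 0/1 treatment
#' indicator (placebo = 0). Defaults are the intranasal-route paths
#' (`a = 6.57` pg/ml, `b = 0.06` rating per pg/ml, `c' = 0.37`).
#'
#' @param n_treat,n_control Group sizes.
#' @param a,b,c_prime Path coefficients.
#' @param y0 Control-group outcome mean (rating points).
#' @param sigma_m,sigma_y Error SDs for mediator (pg/ml) and outcome.
#' @param seed Integer seed.
#' @return Tibble with `x`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n_treat = 56, n_control = 58,
                                    a = 6.57, b = 0.06, c_prime = 0.37,
                                    y0 = 5.5, sigma_m = 8, sigma_y = 1,
                                    seed = 1) {
  withr_seed(seed, {
    x <- c(rep(1, n_treat), rep(0, n_control))
    m <- a * x + rnorm(length(x), 0, sigma_m)
    y <- y0 + c_prime * x + b * m + rnorm(length(x), 0, sigma_y)
    tibble::tibble(x = x, m = m, y = y)
  })
}

# fixed, documented sub-seed rule: adding subjects never perturbs the
# streams of existing ones
subject_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 100003 + index) %% 2147483647)
}

# evaluate a seeded expression without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  force(seed) # evaluate before the state snapshot (seed may be a draw)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cohort generator configuration
#'
#' @param group_sizes Named analyzed-sample sizes per arm (defaults
#'   `intranasal_OT = 56, oral_OT = 57, PLC = 58`).
#' @param n_incomplete,n_technical Numbers of enrolled-but-excluded
#'   subjects (procedure non-completion / technical loss), distributed
#'   round-robin across arms (defaults 5 and 4, i.e. 180 enrolled for the
#'   default arms).
#' @param paths Named list of per-route mediation paths `a`, `b`, `c_prime`
#'   for `intranasal_OT` and `oral_OT`.
#' @param y0 Placebo gentle-touch pleasantness mean.
#' @param sigma_m,sigma_y Mediation error SDs (pg/ml, rating points).
#' @param basal_ot_mean,basal_ot_sd Basal plasma oxytocin, pg/ml.
#' @param effect An [effect_spec()] for the fNIRS forward model.
#' @param design_touch,design_massage Session designs (defaults: 20 blocks,
#'   30 s + 15 s, 6.78 Hz).
#' @param components Which per-subject data to generate: subset of
#'   `c("fnirs", "autonomic")`; ratings and plasma are always generated.
#' @param sessions Which fNIRS sessions to simulate (default both
#'   conditions).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(intranasal_OT = 56, oral_OT = 57,
                                          PLC = 58),
                          n_incomplete = 5, n_technical = 4,
                          paths = list(
                            intranasal_OT = list(a = 6.57, b = 0.06,
                                                 c_prime = 0.37),
                            oral_OT = list(a = 2.41, b = 0.06,
                                           c_prime = 0.50)),
                          y0 = 5.5, sigma_m = 8, sigma_y = 1,
                          basal_ot_mean = 15, basal_ot_sd = 4,
                          effect = effect_spec(),
                          design_touch = make_block_design(
                            condition = "gentle_touch"),
                          design_massage = make_block_design(
                            condition = "medium_massage"),
                          components = c("fnirs", "autonomic"),
                          sessions = c("gentle_touch", "medium_massage")) {
  if (any(group_sizes < 2)) stop("group sizes must be >= 2")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a full study cohort
#'
#' Generates an enrolled roster (analyzed sizes plus excluded subjects),
#' assigns exclusion flags, and per analyzed subject: plasma oxytocin at
#' four timepoints (baseline, +30 min post-treatment, post-session-1,
#' post-session-2) with the post-treatment change following the mediation
#' model `M = a*X + e`, behavioral ratings (pleasantness carrying the
#' mediation outcome `Y = y0 + c'*X + b*M + e`; arousal, intensity,
#' payment-willingness as plausible 1-9 values), and, per `components`,
#' fNIRS recordings for both touch conditions, an RR series and SCR traces.
#' Each subject draws from an independent substream
#' (`subject_seed(master, index)`), so enlarging a cohort leaves existing
#' subjects untouched.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @return An `ot_cohort`: list with `subjects` (tibble, one row per
#'   enrolled subject; list-columns hold recordings and traces), `config`,
#'   `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  gs <- config$group_sizes
  groups <- names(gs)
  # distribute exclusions round-robin over arms, incomplete first
  excl <- rep("none", config$n_incomplete + config$n_technical)
  if (length(excl) > 0)
    excl <- c(rep("incomplete", config$n_incomplete),
              rep("technical", config$n_technical))
  excl_group <- groups[((seq_along(excl) - 1) %% length(groups)) + 1]
  enrolled_group <- c(rep(groups, times = gs), excl_group)
  reasons <- c(rep("none", sum(gs)), excl)
  ord <- withr_seed(seed, sample.int(length(enrolled_group)))
  enrolled_group <- enrolled_group[ord]
  reasons <- reasons[ord]
  n_total <- length(enrolled_group)

  do_fnirs <- "fnirs" %in% config$components
  do_auto <- "autonomic" %in% config$components
  montage <- make_montage()

  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    grp <- enrolled_group[i]
    s <- subject_seed(seed, i)
    row <- withr_seed(s, {
      x <- as.numeric(grp != "PLC")
      pa <- if (grp == "PLC") list(a = 0, b = config$paths[[1]]$b, c_prime = 0)
      else config$paths[[grp]]
      m <- pa$a * x + rnorm(1, 0, config$sigma_m)
      y <- config$y0 + pa$c_prime * x + pa$b * m + rnorm(1, 0, config$sigma_y)
      basal <- max(1, rnorm(1, config$basal_ot_mean, config$basal_ot_sd))
      plasma <- c(
        baseline = basal,
        post_treatment = max(0.1, basal + m),
        post_session1 = max(0.1, basal + 0.7 * m + rnorm(1, 0, 2)),
        post_session2 = max(0.1, basal + 0.5 * m + rnorm(1, 0, 2))
      )
      clamp9 <- function(v) pmin(9, pmax(1, v))
      tibble::tibble(
        id = sprintf("S%03d", i),
        group = grp,
        exclusion_reason = reasons[i],
        plasma_baseline = plasma[["baseline"]],
        plasma_post_treatment = plasma[["post_treatment"]],
        plasma_post_session1 = plasma[["post_session1"]],
        plasma_post_session2 = plasma[["post_session2"]],
        plasma_change = plasma[["post_treatment"]] - plasma[["baseline"]],
        mediator = m,
        pleasantness_gentle_touch = clamp9(y),
        pleasantness_medium_massage = clamp9(rnorm(1, 6, 1)),
        arousal_gentle_touch = clamp9(rnorm(1, 5, 1.5)),
        arousal_medium_massage = clamp9(rnorm(1, 5.5, 1.5)),
        intensity_gentle_touch = clamp9(rnorm(1, 3, 1)),
        intensity_medium_massage = clamp9(rnorm(1, 6, 1)),
        payment_gentle_touch = clamp9(rnorm(1, 5, 2)),
        payment_medium_massage = clamp9(rnorm(1, 5, 2))
      )
    })
    analyzed <- reasons[i] == "none"
    sessions <- config$sessions %||% c("gentle_touch", "medium_massage")
    if (do_fnirs) {
      if ("gentle_touch" %in% sessions && analyzed) {
        row$rec_gentle_touch <- list(simulate_subject_fnirs(
          montage, config$design_touch, config$effect,
          seed = subject_seed(s, 1), group = grp))
      } else row$rec_gentle_touch <- list(NULL)
      if ("medium_massage" %in% sessions && analyzed) {
        row$rec_medium_massage <- list(simulate_subject_fnirs(
          montage, config$design_massage, config$effect,
          seed = subject_seed(s, 2), group = grp))
      } else row$rec_medium_massage <- list(NULL)
    }
    if (do_auto && analyzed) {
      row$rr <- list(simulate_rr(design_duration(config$design_touch),
                                 mean_hr_bpm = max(40, rnorm(1, 70, 6)),
                                 seed = subject_seed(s, 3)))
      row$scr_gentle_touch <- list(simulate_scr(
        config$design_touch, seed = subject_seed(s, 4)))
      row$scr_medium_massage <- list(simulate_scr(
        config$design_massage, seed = subject_seed(s, 5)))
    } else if (do_auto) {
      row$rr <- list(NULL)
      row$scr_gentle_touch <- list(NULL)
      row$scr_medium_massage <- list(NULL)
    }
    subjects[[i]] <- row
  }
  structure(list(subjects = dplyr::bind_rows(subjects),
                 config = config, seed = seed,
                 montage = montage),
            class = "ot_cohort")
}

#' @export
print.ot_cohort <- function(x, ...) {
  tab <- table(x$subjects$group[x$subjects$exclusion_reason == "none"])
  cat("<ot_cohort> ", nrow(x$subjects), " enrolled, ",
      sum(x$subjects$exclusion_reason == "none"), " analyzed (",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Analyzed subjects of a cohort
#' @param cohort An `ot_cohort`.
#' @return Subject tibble restricted to non-excluded subjects.
#' @export
analyzed_subjects <- function(cohort) {
  dplyr::filter(cohort$subjects, .data$exclusion_reason == "none")
}

#' Tidy rating table of a cohort
#' @param cohort An `ot_cohort`.
#' @return Tibble `subject`, `group`, `condition`, `scale`, `rating`
#'   (analyzed subjects only).
#' @export
cohort_ratings <- function(cohort) {
  analyzed_subjects(cohort) |>
    dplyr::select("id", "group",
                  dplyr::matches("^(pleasantness|arousal|intensity|payment)_")) |>
    tidyr::pivot_longer(-c("id", "group"),
                        names_to = c("scale", "condition"),
                        names_pattern = "([a-z]+)_(.*)",
                        values_to = "rating") |>
    dplyr::rename(subject = "id")
}

#' Tidy plasma oxytocin table of a cohort
#' @param cohort An `ot_cohort`.
#' @return Tibble `subject`, `group`, `timepoint`, `pg_ml`.
#' @export
cohort_plasma <- function(cohort) {
  analyzed_subjects(cohort) |>
    dplyr::select("id", "group", dplyr::starts_with("plasma_")) |>
    dplyr::select(-"plasma_change") |>
    tidyr::pivot_longer(dplyr::starts_with("plasma_"),
                        names_to = "timepoint", names_prefix = "plasma_",
                        values_to = "pg_ml") |>
    dplyr::rename(subject = "id")
}

#' Mediation-analysis table for one oxytocin route versus placebo
#'
#' @param cohort An `ot_cohort`.
#' @param route `"intranasal_OT"` or `"oral_OT"`.
#' @return Tibble `subject`, `x` (0/1), `m` (post-treatment plasma change,
#'   pg/ml), `y` (gentle-touch pleasantness).
#' @export
cohort_mediation_table <- function(cohort,
                                   route = c("intranasal_OT", "oral_OT")) {
  route <- match.arg(route)
  analyzed_subjects(cohort) |>
    dplyr::filter(.data$group %in% c(route, "PLC")) |>
    dplyr::transmute(subject = .data$id,
                     x = as.numeric(.data$group == route),
                     m = .data$plasma_change,
                     y = .data$pleasantness_gentle_touch)
}
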