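# shared fixtures built in code

tiny_design <- function(n_blocks = 3, condition = "gentle_touch",
                        sampling_rate = 6.78) {
  make_block_design(n_blocks = n_blocks, stim_s = 30, rest_s = 15,
                    sampling_rate = sampling_rate, condition = condition)
}

# single-channel recording wrapper around a numeric vector
vec_recording <- function(x, fs = 6.78, kind = "concentration") {
  fnirs_recording(matrix(x, nrow = 1), sampling_rate = fs, signal_kind = kind)
}

# effect spec with a single clean mOFC gentle-touch response
amp_only_spec <- function(amplitude = 1, tau_plc = 0, tau_ot = 0) {
  spec <- null_effect_spec()
  spec$amplitude$amplitude[spec$amplitude$roi == "mOFC" &
                             spec$amplitude$condition == "gentle_touch"] <-
    amplitude
  if (tau_ot > 0) {
    spec$prolongation <- tibble::tibble(
      roi = "mOFC", condition = "gentle_touch",
      group = c("PLC", "intranasal_OT"), tau = c(tau_plc, tau_ot))
  }
  spec
}

# small label-free Gaussian feature set for null classification checks
null_features <- function(n_per_group = 25, p = 20, seed = 1) {
  set.seed(seed)
  list(features = matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p),
       labels = rep(c("A", "B"), each = n_per_group))
}
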