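# Shared small fixtures for the suite. Everything is generated in code;
# seeds are fixed so frozen expectations stay valid.

quiet_params <- function(gender = "M", noise_sd = 0, ...) {
  gait_params(paste0("T", gender), gender, noise_sd = noise_sd, ...)
}

# A small in-memory cohort dataset for pipeline tests: short sessions keep
# the suite fast while leaving several full gait cycles per session.
tiny_dataset <- function(n_male = 5, n_female = 5, seed = 11,
                         cue = "dynamic", sessions = 4, duration = 20) {
  co <- sample_cohort(n_male, n_female,
    seed = seed, config = effect_config(cue),
    sessions_per_subject = sessions, session_duration = duration
  )
  simulate_dataset(co)
}

# Windows of iid noise with a planted class mean shift, for model tests
# that need a separable task without the gait machinery.
blob_windows <- function(n_per_class, frames = 10, d = 4, shift = 1, sd = 0.3,
                         seed = 99) {
  set.seed(seed)
  wins <- c(
    lapply(seq_len(n_per_class), function(i) matrix(rnorm(frames * d, shift, sd), frames, d)),
    lapply(seq_len(n_per_class), function(i) matrix(rnorm(frames * d, -shift, sd), frames, d))
  )
  list(windows = wins, labels = rep(c("A", "B"), each = n_per_class))
}

representation_matrix_for_test <- function(seq) {
  gaitlab:::representation_matrix(seq, "position3d")
}
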