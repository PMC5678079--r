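# Small simulated sessions used across the suite. Channel subsets come from
# the default montage and always include the mastoid reference pair so the
# full preprocessing chain can run.

occipital_montage <- function(n = 6L) {
  # O1 Oz O2 PO7 + mastoids, growing towards parietal sites
  picks <- c("O1", "Oz", "O2", "PO7", "PO3", "POz", "Pz", "P3")
  c(picks[seq_len(n - 2L)], "TP9", "TP10")
}

# A fast, clean session: few targets, low acquisition rate, optional noise.
small_sim <- function(session = "120", n_targets = 8L, seed = 1L,
                      noise_sd = 0, alpha_amp_uv = 0, pink_amp_uv = 0,
                      n_channels = 6L, acquisition_rate = 1000, ...) {
  sim_config(session, n_targets = n_targets, trials_per_target = 5L,
             montage = occipital_montage(n_channels),
             acquisition_rate = acquisition_rate,
             noise_sd = noise_sd, alpha_amp_uv = alpha_amp_uv,
             pink_amp_uv = pink_amp_uv, seed = seed, ...)
}

small_config <- function(session = "120", n_targets = 8L, ...) {
  run_config(session, n_targets = n_targets, ...)
}

# Deterministic toy recording for reader / preprocessing tests.
toy_recording <- function(m = 3L, n = 400L, rate = 100,
                          events = data.frame(sample = c(10L, 150L),
                                              label = c(1L, 2L))) {
  set.seed(99)
  eeg_recording(matrix(round(rnorm(m * n), 3), nrow = m), rate,
                c(head(c("A", "B", "C", "D"), m - 2L), "TP9", "TP10")[seq_len(m)],
                events)
}
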