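# Shared fixtures, all generated in code.

# epoched container built directly from a trials x channels x time array
make_epochs <- function(data, fs = 1000, blocks = "LGN1", conditions = "light",
                        montage = default_montage()[seq_len(dim(data)[2]), ],
                        tus_on = conditions %in% c("tus", "light+tus")) {
  n <- dim(data)[1]
  structure(
    list(
      data = data, fs_hz = fs,
      time_ms = seq(-200, 799, by = 1000 / fs)[seq_len(dim(data)[3])],
      labels = data.frame(
        onset_s = seq_len(n), block = rep_len(blocks, n),
        condition = rep_len(conditions, n),
        light_on = rep_len(conditions %in% c("light", "light+tus"), n),
        tus_on = rep_len(tus_on, n)
      ),
      accepted = rep(TRUE, n),
      montage = montage
    ),
    class = "epoched_eeg"
  )
}

# quiet config for deterministic construction tests
silent_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, noise_scale_uV = 0, gamma_burst = NULL,
             blink_rate = 0, tus_artifact_uV = 0, ...)
}

# pink-noise trial matrix via the package's generator
pink_trials <- function(n_trials, n_time = 1000, fs = 1000, seed = 1L) {
  tusvep:::with_rng_seed(seed, {
    t(vapply(seq_len(n_trials),
             function(i) tusvep:::pink_noise(n_time, fs), numeric(n_time)))
  })
}
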