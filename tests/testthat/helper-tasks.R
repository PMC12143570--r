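# Shared fixtures: small task configurations used across test files.

# Short multisensory task. At n = 40 the sparsity bound k/(n+k-1) reaches
# 0.17 for k = 8, so short tasks run denser (p_e = 0.2) than the standard
# long task; tests that need the standard sparsity pass p_e explicitly.
short_task <- function(k = 1, n = 40, p_e = 0.2, ...) {
  task_spec(k, n = n, p_e = p_e, ...)
}

# Tiny task for brute-force oracle work: n = 4, Levy lengths on {1, 2};
# sparsity must exceed E[L] / (n - 1 + E[L]) = 0.286, so use 0.4.
tiny_task <- function(p_e = 0.4) {
  task_config(n = 4L, p_e = p_e,
              burst_model = burst_length_pmf("levy", l_max = 2))
}

# The worked 2-channel, 4-step observation sequence used to illustrate the
# window-count features: channel 1 = (-1,-1,-1,1), channel 2 = (-1,-1,-1,0).
worked_example_trials <- function() {
  tibble::tibble(
    trial_id = 1L,
    t = 1:4,
    m = 1L,
    e = 0L,
    x1 = c(-1L, -1L, -1L, 1L),
    x2 = c(-1L, -1L, -1L, 0L)
  )
}

# Shuffle time steps within each trial, keeping channels aligned.
shuffle_time <- function(trials, seed = 1) {
  set.seed(seed)
  parts <- lapply(split(trials, trials$trial_id), function(df) {
    df2 <- df[sample.int(nrow(df)), ]
    df2$t <- df$t
    df2
  })
  out <- dplyr::bind_rows(parts)
  out[order(out$trial_id, out$t), ]
}
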