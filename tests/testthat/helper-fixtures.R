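# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

# A flat sweep with optional inserted events, for detector tests.
flat_sweep <- function(duration_ms = 100, fs = 50e3, level = -60,
                       t0_offset = 0, noise_sd = 0, seed = 1,
                       stimulus = "spontaneous") {
  n <- round(duration_ms / 1000 * fs)
  v <- rep(level, n)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(n, 0, noise_sd)
  }
  sweep_trace(v, fs, t0_offset = t0_offset, stimulus = stimulus,
              junction_corrected = TRUE)
}

# Insert a stereotyped spike (1 ms gaussian bump) peaking at `peak_vm`.
insert_test_spike <- function(sweep, time_ms, peak_vm) {
  t <- sweep_times(sweep)
  bump <- exp(-((t - time_ms) / 0.12)^2)
  base <- sweep$samples[which.min(abs(t - time_ms))]
  idx <- bump > 1e-4
  sweep$samples[idx] <- pmax(sweep$samples[idx],
                             base + (peak_vm - base) * bump[idx])
  sweep
}

# Small tone stimulus shared by constructed-evoked tests.
test_tone <- function(n_reps = 5, duration = 50) {
  tone_stimulus("ipsi", 8000, level_ipsi = 70, duration = duration,
                n_reps = n_reps)
}
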