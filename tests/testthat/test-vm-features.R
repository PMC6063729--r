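test_that("preprocessing attenuates sub-cutoff frequencies and keeps fast ones", {
  fs <- 20e3
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  slow <- sweep_trace(-60 + 5 * sin(2 * pi * 1 * t), fs)   # 1 Hz
  out <- preprocess_spontaneous(slow)
  atten_db <- 20 * log10(sd(5 * sin(2 * pi * 1 * t)) / sd(out))
  expect_gt(atten_db, 20)

  zero <- preprocess_spontaneous(sweep_trace(rep(0, fs), fs))
  expect_equal(max(abs(zero)), 0, tolerance = 1e-9)

  fast <- sweep_trace(-60 + 10 * sin(2 * pi * 300 * t), fs)  # 300 Hz, large
  outf <- preprocess_spontaneous(fast)
  expect_lt(abs(sd(outf) / sd(10 * sin(2 * pi * 300 * t)) - 1), 0.1)

  short <- sweep_trace(rep(-60, 1000), 50e3)                 # 20 ms
  expect_error(preprocess_spontaneous(short), "insufficient")
})

test_that("amplitude spectrum localizes tones and rejects flat traces", {
  fs <- 50e3
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  sp <- amplitude_spectrum(sin(2 * pi * 100 * t), fs, smooth = "none")
  expect_equal(sp$frequencies[which.max(sp$normalized_amplitude)], 100)
  expect_equal(max(sp$normalized_amplitude), 1)

  two <- sin(2 * pi * 100 * t) + sin(2 * pi * 400 * t)
  sp2 <- amplitude_spectrum(two, fs, smooth = "none")
  a100 <- sp2$normalized_amplitude[sp2$frequencies == 100]
  a400 <- sp2$normalized_amplitude[sp2$frequencies == 400]
  expect_equal(a100, 1, tolerance = 1e-9)   # equal components tie at 1
  expect_equal(a400, 1, tolerance = 1e-9)

  expect_error(amplitude_spectrum(rep(3, 1000), fs), "flat spectrum")
})

test_that("upper cutoff hits the closed-form -6 dB point of a single pole", {
  f <- seq(10, 2000, by = 2)
  prof <- 1 / sqrt(1 + (f / 200)^2)
  sp <- structure(list(frequencies = f,
                       normalized_amplitude = prof / max(prof),
                       smooth = "none", upper_cutoff = NA_real_),
                  class = "lso_spectrum")
  # closed form: crossing of fraction*max(prof) on the sampled profile
  target <- 0.5 * max(prof)
  expected <- 200 * sqrt(1 / target^2 - 1)
  expect_lt(abs(upper_cutoff(sp) - expected), 2)   # within one bin

  rect <- structure(list(frequencies = f,
                         normalized_amplitude = as.numeric(f <= 500),
                         smooth = "none", upper_cutoff = NA_real_),
                    class = "lso_spectrum")
  expect_lt(abs(upper_cutoff(rect) - 500), 2)

  flat_high <- structure(list(frequencies = f,
                              normalized_amplitude = rep(1, length(f)),
                              smooth = "none", upper_cutoff = NA_real_),
                         class = "lso_spectrum")
  expect_error(upper_cutoff(flat_high), "cutoff not reached")
})

test_that("spectral cutoff is scale invariant and decreases with PSP width", {
  g <- gen_spontaneous(principal_archetype(), 2, seed = 21)
  tr <- preprocess_spontaneous(g$sweep)
  base <- upper_cutoff(amplitude_spectrum(tr, 50e3))
  expect_equal(upper_cutoff(amplitude_spectrum(tr * 3.7, 50e3)), base,
               tolerance = 1e-12)

  cuts <- vapply(c(0.5, 1, 2, 4, 8), function(hw) {
    p <- principal_archetype(epsp_half_width = hw, ipsp_half_width = 2 * hw)
    spectral_cutoff(gen_spontaneous(p, 2, seed = 33)$sweep)$upper_cutoff
  }, numeric(1))
  expect_true(all(diff(cuts) < 0))
})

test_that("spike detection finds inserted templates and ignores noise", {
  s <- flat_sweep(200, noise_sd = 0.3, seed = 2)
  truth <- c(40, 90, 151.3)
  for (tt in truth) s <- insert_test_spike(s, tt, -32)      # ~28 mV spikes
  det <- detect_spikes(s)
  expect_equal(nrow(det), 3)
  expect_true(all(abs(det$time - truth) < 0.2))

  noise_only <- flat_sweep(500, noise_sd = 1, seed = 9)
  expect_equal(nrow(detect_spikes(noise_only)), 0)

  close_pair <- flat_sweep(50, noise_sd = 0)
  close_pair <- insert_test_spike(close_pair, 20, -30)
  close_pair <- insert_test_spike(close_pair, 20.5, -30)
  expect_equal(nrow(detect_spikes(close_pair)), 1)          # refractory rule
})

test_that("AP amplitude is peak minus the 2 ms file baseline", {
  s <- flat_sweep(60, level = -58, stimulus = test_tone(1))
  s <- insert_test_spike(s, 30, -30)
  expect_equal(ap_amplitude(list(s)), 28, tolerance = 0.01)

  # baseline drift after the 2 ms window must not bias the measure
  d <- flat_sweep(60, level = -58, stimulus = test_tone(1))
  t <- sweep_times(d)
  d$samples[t >= 5] <- d$samples[t >= 5] + 5
  d <- insert_test_spike(d, 30, -30)
  expect_equal(ap_amplitude(list(d)), 28, tolerance = 0.01)

  expect_error(ap_amplitude(list(flat_sweep(60))), "no APs")
})

test_that("median evoked response equals the per-sample sort median", {
  mk <- function(level) flat_sweep(20, level = level, stimulus = test_tone())
  med <- median_evoked(list(mk(-60), mk(-55), mk(-70)))
  expect_equal(unique(med$samples), -60)

  set.seed(14)
  sweeps <- lapply(1:7, function(i) {
    s <- flat_sweep(20, noise_sd = 1, seed = 100 + i, stimulus = test_tone())
    s
  })
  med2 <- median_evoked(sweeps)
  mat <- do.call(cbind, lapply(sweeps, function(s) s$samples))
  oracle <- apply(mat, 1, function(row) {
    sr <- sort(row); n <- length(sr)
    if (n %% 2) sr[(n + 1) / 2] else mean(sr[n / 2 + 0:1])
  })
  expect_identical(med2$samples, oracle)

  # one spiking outlier barely moves the median
  clean <- lapply(1:6, function(i)
    flat_sweep(20, noise_sd = 0.2, seed = i, stimulus = test_tone()))
  spiky <- insert_test_spike(clean[[1]], 10, 5)
  with_out <- median_evoked(c(clean[-1], list(spiky)))
  without <- median_evoked(clean)
  expect_lt(max(abs(with_out$samples - without$samples)), 1)

  expect_error(median_evoked(list(mk(-60), mk(-60))), ">= 3")
  ragged <- list(mk(-60), mk(-60), flat_sweep(10, stimulus = test_tone()))
  expect_error(median_evoked(ragged), "ragged")
})

test_that("peak-to-sustained handles square pulses, spikes and exclusions", {
  fs <- 50e3
  mk_square <- function() {
    s <- flat_sweep(70, level = -60, t0_offset = -10, stimulus = test_tone())
    t <- sweep_times(s)
    s$samples[t >= 0 & t < 50] <- -52            # 8 mV square depolarization
    s
  }
  res <- peak_to_sustained(list(mk_square(), mk_square(), mk_square()))
  expect_equal(res$ratio, 1, tolerance = 1e-6)

  # onset bump 8 mV within [5,15), sustained plateau 1 mV
  mk_shaped <- function() {
    s <- flat_sweep(70, level = -60, t0_offset = -10, stimulus = test_tone())
    t <- sweep_times(s)
    s$samples <- s$samples + 8 * exp(-((t - 8) / 2)^2) +
      ifelse(t >= 15 & t < 50, 1, 0)
    s
  }
  res2 <- peak_to_sustained(list(mk_shaped(), mk_shaped(), mk_shaped()))
  expect_equal(res2$ratio, 8, tolerance = 0.1 * 8)

  # every rep spiking inside the onset window -> no usable repetitions
  spiky <- lapply(1:4, function(i) insert_test_spike(mk_square(), 8, 10))
  expect_error(peak_to_sustained(spiky), "insufficient spike-free")
})

test_that("input resistance recovers R and the sag ratio from ideal steps", {
  quiet <- principal_archetype(noise_sd = 0, sag_fraction = 0, r_in = 60,
                               membrane_tau = 1)
  s <- gen_current_step(quiet, current_step(-500), seed = 1)
  r <- input_resistance(s)
  expect_equal(r$r_steady, 60, tolerance = 0.01)
  expect_equal(r$r_peak, 60, tolerance = 0.01)

  saggy <- principal_archetype(noise_sd = 0, sag_fraction = 0.2, r_in = 60,
                               membrane_tau = 1)
  s2 <- gen_current_step(saggy, current_step(-500), seed = 1)
  r2 <- input_resistance(s2)
  expect_equal(r2$r_peak / r2$r_steady, 1 / (1 - 0.2), tolerance = 0.03)

  s3 <- gen_current_step(quiet, current_step(500), seed = 1)
  expect_error(input_resistance(s3), "hyperpolarizing")
})
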