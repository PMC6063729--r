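test_that("PSP kernel has the requested FWHM and exact peak", {
  fs <- 100e3
  k <- psp_kernel("epsp", 5, 0.6, fs)
  expect_equal(max(k), 5)
  half <- max(k) / 2
  above <- which(k >= half)
  fwhm <- (above[length(above)] - above[1]) / fs * 1000
  expect_lt(abs(fwhm - 0.6) / 0.6, 0.02)

  ki <- psp_kernel("ipsp", 5, 0.6, fs)
  expect_equal(min(ki), -5)
  expect_equal(ki, -k)

  expect_error(psp_kernel("epsp", 5, 0.01, 50e3), "undersampled")
})

test_that("spontaneous generation is deterministic and event-conserving", {
  p <- principal_archetype()
  quiet <- principal_archetype(epsp_rate_spont = 0, ipsp_rate_spont = 0,
                               noise_sd = 0)
  g0 <- gen_spontaneous(quiet, 0.5, seed = 1)
  expect_equal(unique(g0$sweep$samples), quiet$resting_vm)

  g1 <- gen_spontaneous(p, 1, seed = 42)
  g2 <- gen_spontaneous(p, 1, seed = 42)
  expect_identical(g1$sweep$samples, g2$sweep$samples)

  # rate conservation: EPSP count within 3 SD of lambda*T
  p100 <- principal_archetype(epsp_rate_spont = 100, ipsp_rate_spont = 0)
  g4 <- gen_spontaneous(p100, 4, seed = 5)
  n_ep <- sum(g4$truth$events$kind == "epsp")
  expect_lt(abs(n_ep - 400), 3 * sqrt(400))

  expect_error(gen_spontaneous(p, 0.1), "duration")
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_spontaneous(principal_archetype(), 0.5, seed = 9))
  expect_identical(.Random.seed, before)
  invisible(gen_cohort(1, 0, seed = 2, spont_duration_s = 0.5,
                       n_reps = 3, protocols = "spontaneous"))
  expect_identical(.Random.seed, before)
})

test_that("PSP counts are Poisson distributed (KS on 200 draws)", {
  lambda <- 60 * 0.5                      # 60 events/s for 0.5 s
  p <- principal_archetype(epsp_rate_spont = 60, ipsp_rate_spont = 0,
                           noise_sd = 0)
  counts <- vapply(1:200, function(s) {
    sum(gen_spontaneous(p, 0.5, seed = 1000 + s)$truth$events$kind == "epsp")
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(counts, function(q)
    stats::ppois(q, lambda)))
  expect_gt(ks$p.value, 0.01)
})

test_that("principal tone responses are onset-only with jittered latency", {
  p <- principal_archetype()
  stim <- tone_stimulus("ipsi", 8000, level_ipsi = 70, duration = 50,
                        n_reps = 30)
  g <- gen_tone_response(p, stim, seed = 5)
  n_one <- sum(vapply(g$truth$spike_times, function(tt)
    length(tt) == 1 && tt >= 0 && tt < 10, logical(1)))
  expect_gte(n_one / 30, 0.9)

  cstim <- tone_stimulus("contra", 8000, level_contra = 70, duration = 50,
                         n_reps = 10)
  gc <- gen_tone_response(p, cstim, seed = 6)
  expect_equal(sum(lengths(gc$truth$spike_times)), 0)
  med <- median_evoked(gc$sweeps)
  t <- sweep_times(med)
  base <- median(med$samples[t < 0])
  lat <- gc$truth$ipsp_latency
  expect_lt(mean(med$samples[t >= lat & t < 10]) - base, 0)  # hyperpolarized
})

test_that("IPSP latency trades linearly with contralateral level", {
  p <- principal_archetype()          # latency 6 ms at 50 dB, -0.12 ms/dB
  levels <- seq(40, 85, by = 5)
  lat <- vapply(levels, function(L) {
    stim <- tone_stimulus("contra", 8000, level_contra = L, duration = 25,
                          n_reps = 1)
    gen_tone_response(p, stim, seed = 3)$truth$ipsp_latency
  }, numeric(1))
  slope <- coef(lm(lat ~ levels))[["levels"]]
  expect_lt(abs(slope - (-0.12)) / 0.12, 0.05)
})

test_that("chopper trains match the configured gamma-renewal statistics", {
  np <- nonprincipal_archetype(chopper_isi_mean = 4, chopper_isi_cv = 0.2)
  stim <- tone_stimulus("ipsi", 6000, level_ipsi = 70, duration = 50,
                        n_reps = 50)
  g <- gen_tone_response(np, stim, seed = 8)
  isis <- unlist(lapply(g$truth$spike_times, diff))
  expect_lt(abs(mean(isis) - 4) / 4, 0.1)
  expect_lt(abs(sd(isis) / mean(isis) - 0.2) / 0.2, 0.15)
})

test_that("ILD series suppresses spiking monotonically toward the truth", {
  p <- principal_archetype()
  # contra far below threshold (ILD -50): the monaural spike probability;
  # contra far above (ILD +30): silence
  g <- gen_ild_series(p, 8000, 70, c(20, 60, 100), n_reps = 30, seed = 2)
  rates <- vapply(seq_along(g$sweep_sets), function(i)
    mean(lengths(g$truth$spike_times[[i]])), numeric(1))
  expect_lt(abs(rates[1] - 0.97), 3 * sqrt(0.97 * 0.03 / 30))
  expect_lt(rates[3], 0.05)
  expect_equal(g$truth$ild, c(-50, -10, 30))
  expect_error(gen_ild_series(p, 8000, 70, c(0, 10), 5, 1), ">= 3")
})

test_that("current steps follow Ohm's law with a controlled sag", {
  quiet <- principal_archetype(noise_sd = 0, sag_fraction = 0, r_in = 60,
                               membrane_tau = 1)
  flat <- gen_current_step(quiet, current_step(0), seed = 1)
  expect_equal(unique(flat$samples), quiet$resting_vm)

  s <- gen_current_step(quiet, current_step(-500), seed = 1)
  t <- sweep_times(s)
  steady <- median(s$samples[t >= 90 & t < 100]) -
    median(s$samples[t < 0])
  expect_equal(steady, -30, tolerance = 0.01)    # -0.5 nA * 60 MOhm

  saggy <- principal_archetype(noise_sd = 0, sag_fraction = 0.2, r_in = 60,
                               membrane_tau = 1)
  s2 <- gen_current_step(saggy, current_step(-500), seed = 1)
  t2 <- sweep_times(s2)
  base <- median(s2$samples[t2 < 0])
  peak <- min(s2$samples[t2 >= 0 & t2 < 100]) - base
  stead <- median(s2$samples[t2 >= 90 & t2 < 100]) - base
  expect_equal(peak / stead, 1 / (1 - 0.2), tolerance = 0.02)

  expect_error(gen_current_step(quiet, current_step(5000)), "3000")
})

test_that("cohorts carry ground truth and all requested protocols", {
  coh <- gen_cohort(2, 2, seed = 1, spont_duration_s = 0.5, n_reps = 3)
  expect_length(coh, 4)
  labels <- vapply(coh, function(el) el$truth$class_label, character(1))
  expect_equal(labels, c("principal", "principal",
                         "non_principal", "non_principal"))
  expect_setequal(names(coh[[1]]$cell$sweeps),
                  c("spontaneous", "ipsi_tone", "contra_tone", "ild",
                    "current_step"))
  # half-width draws respect the documented class ranges
  hws <- vapply(coh, function(el) el$truth$params$epsp_half_width, numeric(1))
  expect_true(all(hws[1:2] >= 0.4 & hws[1:2] <= 0.9))
  expect_true(all(hws[3:4] >= 2 & hws[3:4] <= 6))
})
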