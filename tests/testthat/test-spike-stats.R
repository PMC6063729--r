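test_that("extract_trains references detected spikes to stimulus onset", {
  p <- principal_archetype()
  stim <- tone_stimulus("ipsi", 8000, level_ipsi = 70, duration = 50,
                        n_reps = 30)
  g <- gen_tone_response(p, stim, seed = 11)
  tr <- extract_trains(g$sweeps)
  expect_length(tr$trains, 30)
  first <- vapply(tr$trains, function(tt)
    if (length(tt)) tt[1] else NA_real_, numeric(1))
  expect_true(all(first[!is.na(first)] >= 0 & first[!is.na(first)] < 10))

  # invariant under repetition permutation
  perm <- c(17, 3, 30, 1:2, 4:16, 18:29)
  tr2 <- extract_trains(g$sweeps[perm])
  expect_identical(tr2$trains, tr$trains[perm])

  spont <- replicate(3, flat_sweep(100, noise_sd = 0.3), simplify = FALSE)
  expect_true(all(lengths(extract_trains(spont)$trains) == 0))
})

test_that("window_rate matches counting and partitions add up", {
  tr <- spike_trains(rep(list(5), 10), test_tone())   # 1 spike at 5 ms each
  expect_equal(window_rate(tr, c(0, 10)), 100)
  expect_equal(window_rate(tr, c(10, 25)), 0)

  set.seed(20)
  rnd <- spike_trains(lapply(1:25, function(i) sort(runif(12, 0, 50))),
                      test_tone())
  w <- c(7.3, 22.1)
  oracle <- mean(vapply(rnd$trains, function(tt)
    sum(tt >= w[1] & tt < w[2]), numeric(1))) / ((w[2] - w[1]) / 1000)
  expect_identical(window_rate(rnd, w), oracle)

  # rates over a partition of [0, 50) combine to the total rate
  cuts <- c(0, 10, 25, 50)
  parts <- vapply(1:3, function(i)
    window_rate(rnd, cuts[i + 0:1]), numeric(1))
  total <- window_rate(rnd, c(0, 50))
  expect_equal(sum(parts * diff(cuts)) / 50, total)
})

test_that("onset fraction separates onset from homogeneous firing", {
  onset <- spike_trains(rep(list(c(4.2)), 20), test_tone())
  expect_equal(onset_fraction(onset), 1)

  set.seed(3)
  hom <- spike_trains(lapply(1:40, function(i) sort(runif(20, 0, 50))),
                      test_tone())
  f <- onset_fraction(hom)
  expect_lt(abs(f - 0.2), 3 * sqrt(0.2 * 0.8 / 800))

  expect_error(onset_fraction(spike_trains(list(numeric(0)), test_tone())),
               "zero spikes")
})

test_that("regularity analysis recovers renewal statistics per bin", {
  # gamma renewal trains built directly (independent of the generator)
  set.seed(77)
  cv <- 0.2; mu <- 4; shape <- 1 / cv^2
  trains <- lapply(1:50, function(i) {
    tt <- 1.5
    while (tail(tt, 1) < 50)
      tt <- c(tt, tail(tt, 1) + rgamma(1, shape, scale = mu / shape))
    tt[tt < 50]
  })
  rc <- regularity_curve(spike_trains(trains, test_tone()))
  sus <- rc[rc$included & rc$bin_center > 10 & rc$bin_center < 45, ]
  expect_gt(nrow(sus), 10)
  expect_lt(abs(mean(sus$cv) - cv) / cv, 0.15)
  expect_lt(abs(mean(sus$mean_isi) - mu) / mu, 0.1)

  # perfectly periodic -> CV 0 in all included bins
  per <- spike_trains(rep(list(seq(2, 48, by = 4)), 20), test_tone())
  rp <- regularity_curve(per)
  expect_true(all(rp$cv[rp$included] == 0))
  expect_true(any(rp$included))

  # single-spike reps leave no includable bins but are not an error
  ons <- spike_trains(c(rep(list(4), 30), list(c(4, 9))), test_tone())
  ro <- suppressWarnings(regularity_curve(ons))
  expect_false(any(ro$included))

  none <- spike_trains(rep(list(4), 20), test_tone())
  expect_error(suppressWarnings(regularity_curve(none)), "no intervals")
})

test_that("regularity CV approaches 1 for Poisson trains", {
  set.seed(99)
  trains <- lapply(1:100, function(i) sort(runif(rpois(1, 40), 0, 50)))
  rc <- regularity_curve(spike_trains(trains, test_tone()))
  inc <- rc[rc$included & rc$bin_center > 5 & rc$bin_center < 40, ]
  # pooled CV across included bins, allowing 3 SE of the per-bin estimate
  expect_lt(abs(mean(inc$cv) - 1), 3 * sd(inc$cv) / sqrt(nrow(inc)) + 0.1)
})

test_that("regularity is invariant to a uniform time shift", {
  set.seed(41)
  trains <- lapply(1:30, function(i) sort(runif(15, 0, 40)))
  a <- regularity_curve(spike_trains(trains, test_tone()), t_range = c(0, 40))
  b <- regularity_curve(spike_trains(lapply(trains, `+`, 7), test_tone()),
                        t_range = c(7, 47))
  expect_equal(b$cv, a$cv)
  expect_equal(b$rep_fraction, a$rep_fraction)
})

test_that("best frequency is the argmax with low-frequency tie break", {
  expect_equal(bf_from_counts(c(4000, 8000, 16000), c(10, 25, 12)), 8000)
  expect_equal(bf_from_counts(c(8000, 4000), c(10, 10)), 4000)
  expect_error(bf_from_counts(c(4000, 8000), c(0, 0)), "zero")
  expect_error(bf_from_counts(4000, 10), ">= 2")

  # synthetic tuning profile with a known peak
  f <- c(2, 4, 8, 16, 32) * 1000
  counts <- round(40 * exp(-(log2(f / 8000))^2))
  expect_equal(bf_from_counts(f, counts), 8000)
})
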