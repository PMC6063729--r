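test_that("printed group summaries reproduce the population statistics", {
  # upper cutoff frequency: 528.7 +- 66.5 (n=5) vs 131.4 +- 15.5 Hz (n=7)
  a <- group_summary(n = 5, mean = 528.7, sem = 66.5)
  b <- group_summary(n = 7, mean = 131.4, sem = 15.5)
  tt <- pooled_t_from_summaries(a, b)
  expect_equal(tt$df, 10)
  expect_lt(abs(tt$statistic - 6.83), 0.01)   # inputs printed to 1 decimal
  expect_lt(tt$p_two_tailed, 1e-4)
  expect_lt(abs(hedges_g(a, b) - 4.00), 0.005)

  # AP amplitude: 28.3 +- 5.2 (n=5) vs 66.3 +- 4.5 mV (n=7), within 1%
  ap_a <- group_summary(n = 5, mean = 28.3, sem = 5.2)
  ap_b <- group_summary(n = 7, mean = 66.3, sem = 4.5)
  tt2 <- pooled_t_from_summaries(ap_a, ap_b)
  expect_lt(abs(tt2$statistic - (-5.48)) / 5.48, 0.01)
  expect_lt(abs(abs(hedges_g(ap_a, ap_b)) - 3.21) / 3.21, 0.01)
})

test_that("summary-path t equals the raw-sample t, and g behaves", {
  set.seed(31)
  x <- rnorm(9, 10, 2); y <- rnorm(13, 12, 3)
  ours <- pooled_t_from_summaries(group_summary(x), group_summary(y))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-10)

  same <- group_summary(n = 6, mean = 5, sem = 1)
  expect_equal(pooled_t_from_summaries(same, same)$statistic, 0)
  expect_equal(hedges_g(same, same), 0)

  g_raw <- hedges_g(group_summary(x), group_summary(y))
  g_cor <- hedges_g(group_summary(x), group_summary(y), correct = TRUE)
  expect_equal(g_cor / g_raw, 1 - 3 / (4 * 20 - 1))
})

test_that("pearson_r matches cor.test and the printed r/p pair", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 3)$r, 1)
  expect_lt(pearson_r(x, 2 * x + 3)$p_two_tailed, 1e-12)

  set.seed(17)
  u <- rnorm(11); v <- 0.5 * u + rnorm(11)
  ours <- pearson_r(u, v)
  ref <- cor.test(u, v)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-10)

  # a correlation of -0.64 over 11 cells is significant at ~0.035
  r <- -0.64; n <- 11
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), n - 2)
  expect_lt(abs(p - 0.035), 0.002)

  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), ">= 3")
})

test_that("feature extraction reflects the archetype contrasts", {
  coh <- gen_cohort(1, 1, seed = 6,
                    protocols = c("spontaneous", "ipsi_tone"))
  fp <- extract_features(coh[[1]]$cell)
  fn <- extract_features(coh[[2]]$cell)
  expect_gt(fp$upper_cutoff, 300)
  expect_lt(fp$ap_amplitude, 45)
  expect_lt(fn$upper_cutoff, 250)
  expect_gt(fn$ap_amplitude, 45)
  # optional protocols absent -> NA, never silent defaults
  expect_true(is.na(fp$peak_to_sustained_contra))
  expect_true(is.na(fp$r_in_steady))

  no_spont <- coh[[1]]$cell
  no_spont$sweeps$spontaneous <- NULL
  expect_error(extract_features(no_spont), "spontaneous")
})

test_that("clustering is anchor-aware, order/scale invariant, honest about ties", {
  set.seed(9)
  n_p <- 9; n_n <- 12
  feats <- data.frame(
    cell_id = sprintf("c%02d", 1:(n_p + n_n)),
    upper_cutoff = c(rnorm(n_p, 500, 80), rnorm(n_n, 130, 30)),
    ap_amplitude = c(rnorm(n_p, 28, 6), rnorm(n_n, 66, 8)))
  truth <- rep(c("principal", "non_principal"), c(n_p, n_n))

  cl <- cluster_cells(feats)
  expect_equal(cl$label, truth)
  expect_true(all(cl$confidence > 0))

  # anchors mirroring a partially labeled cohort: 5 + 7 known, 9 unlabeled
  anchors <- rep(NA_character_, n_p + n_n)
  anchors[1:5] <- "principal"; anchors[10:16] <- "non_principal"
  cla <- cluster_cells(feats, anchors = anchors)
  expect_false(any(cla$label == "unassignable"))
  expect_equal(cla$label, truth)

  # order invariance
  perm <- sample(n_p + n_n)
  clp <- cluster_cells(feats[perm, ])
  expect_equal(clp$label, truth[perm])

  # affine rescaling of a raw feature changes nothing (z-scoring)
  resc <- feats
  resc$ap_amplitude <- resc$ap_amplitude * 3 + 12
  expect_equal(cluster_cells(resc)$label, cl$label)

  # identical feature vectors with opposing anchors get ~zero confidence
  twin <- data.frame(upper_cutoff = c(300, 300, 500, 120, 130, 450),
                     ap_amplitude = c(40, 40, 28, 60, 62, 30))
  cft <- cluster_cells(twin, anchors = c("principal", "non_principal",
                                         NA, NA, NA, NA))
  expect_lt(max(cft$confidence[1:2]), 1e-6)

  # too few cells for a 2-group solution
  one <- cluster_cells(data.frame(upper_cutoff = 400, ap_amplitude = 30))
  expect_equal(one$label, "unassignable")
})
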