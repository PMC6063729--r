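#!/usr/bin/env Rscript
# Population analysis: two-feature classification (log cutoff frequency x
# AP amplitude), reproduction of the reported group statistics from their
# printed summaries, and the rate-vs-hyperpolarization correlation.

library(lsoephys)

seed <- 1
dir.create("results", showWarnings = FALSE)

if (!file.exists("results/features.csv"))
  stop("run analysis/02_membrane_features.R first")
feats <- read.csv("results/features.csv")
truth <- ifelse(feats$true_class == "principal", "principal", "non_principal")

# unsupervised 2-means and anchor-based assignment (5 + 7 anchors, the
# partially labeled situation of a real cohort)
cl <- cluster_cells(feats)
anchors <- rep(NA_character_, nrow(feats))
anchors[which(truth == "principal")[1:5]] <- "principal"
anchors[which(truth == "non_principal")[1:7]] <- "non_principal"
cla <- cluster_cells(feats, anchors = anchors)
classes <- data.frame(cell_id = feats$cell_id, true_class = truth,
                      kmeans_label = cl$label,
                      kmeans_confidence = round(cl$confidence, 3),
                      anchored_label = cla$label,
                      anchored_confidence = round(cla$confidence, 3))
write.csv(classes, "results/classes.csv", row.names = FALSE)
message(sprintf("2-means accuracy: %.0f%%; anchored accuracy: %.0f%%",
                100 * mean(cl$label == truth),
                100 * mean(cla$label == truth)))

# reported group statistics recomputed from printed summaries
printed <- rbind(
  data.frame(comparison = "upper_cutoff_hz",
             t = pooled_t_from_summaries(
               group_summary(n = 5, mean = 528.7, sem = 66.5),
               group_summary(n = 7, mean = 131.4, sem = 15.5))$statistic,
             hedges_g = hedges_g(
               group_summary(n = 5, mean = 528.7, sem = 66.5),
               group_summary(n = 7, mean = 131.4, sem = 15.5))),
  data.frame(comparison = "ap_amplitude_mv",
             t = pooled_t_from_summaries(
               group_summary(n = 5, mean = 28.3, sem = 5.2),
               group_summary(n = 7, mean = 66.3, sem = 4.5))$statistic,
             hedges_g = hedges_g(
               group_summary(n = 5, mean = 28.3, sem = 5.2),
               group_summary(n = 7, mean = 66.3, sem = 4.5))))
write.csv(printed, "results/printed_stats.csv", row.names = FALSE)
message(sprintf("printed-summary statistics: t10 = %.2f / g = %.2f (cutoff), t10 = %.2f / g = %.2f (AP)",
                printed$t[1], printed$hedges_g[1],
                printed$t[2], printed$hedges_g[2]))

# evoked ipsi spike rate vs sustained contra hyperpolarization
coh <- gen_cohort(6, 6, seed = seed + 5,
                  protocols = c("ipsi_tone", "contra_tone"))
rate <- vapply(coh, function(el)
  window_rate(extract_trains(el$cell$sweeps$ipsi_tone), c(0, 50)),
  numeric(1))
hyp <- vapply(coh, function(el) {
  med <- median_evoked(el$cell$sweeps$contra_tone)
  t <- sweep_times(med)
  mean(med$samples[t >= 10 & t < 25]) - median(med$samples[t < 0])
}, numeric(1))
corr <- pearson_r(rate, hyp)
write.csv(data.frame(cell_id = vapply(coh, function(el) el$cell$cell_id,
                                      character(1)),
                     ipsi_rate = rate, sustained_hyperpol_mv = hyp),
          "results/rate_vs_hyperpol.csv", row.names = FALSE)
message(sprintf("rate vs hyperpolarization: r = %.2f, p = %.3f (n = %d)",
                corr$r, corr$p_two_tailed, length(rate)))
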