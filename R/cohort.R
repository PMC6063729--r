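#' Extract the physiology feature vector of a cell
#'
#' Composes the membrane-potential operations: spectral upper cutoff from
#' the spontaneous protocol, AP amplitude from the ipsi-tone protocol,
#' peak-to-sustained ratios from ipsi- and contra-tone protocols, and input
#' resistances from hyperpolarizing current steps. Missing optional
#' protocols yield `NA` fields; a missing spontaneous or ipsi-tone protocol
#' is an error.
#'
#' @param cell an `lso_cell` with at least `spontaneous` and `ipsi_tone`
#'   protocols.
#' @return one-row data.frame: `cell_id`, `upper_cutoff`, `ap_amplitude`,
#'   `peak_to_sustained_ipsi`, `peak_to_sustained_contra`,
#'   `sustained_hyperpol`, `r_in_steady`, `r_in_peak`.
#' @export
extract_features <- function(cell) {
  stopifnot(inherits(cell, "lso_cell"))
  for (need in c("spontaneous", "ipsi_tone")) {
    if (is.null(cell$sweeps[[need]]))
      stop("cell ", cell$cell_id, " lacks required protocol: ", need)
  }
  cutoff <- spectral_cutoff(cell$sweeps$spontaneous[[1]])$upper_cutoff
  apamp <- tryCatch(ap_amplitude(cell$sweeps$ipsi_tone),
                    error = function(e) NA_real_)
  pts <- function(proto) {
    if (is.null(cell$sweeps[[proto]])) return(NA_real_)
    tryCatch(peak_to_sustained(cell$sweeps[[proto]])$ratio,
             error = function(e) NA_real_)
  }
  sus_hyp <- NA_real_
  if (!is.null(cell$sweeps$contra_tone)) {
    sus_hyp <- tryCatch({
      med <- median_evoked(cell$sweeps$contra_tone)
      t <- sweep_times(med)
      base <- stats::median(med$samples[t < 0])
      mean(med$samples[t >= 10 & t < 25]) - base  # negative = hyperpolarized
    }, error = function(e) NA_real_)
  }
  r_st <- r_pk <- NA_real_
  if (!is.null(cell$sweeps$current_step)) {
    hyper <- Filter(function(s) s$stimulus$amplitude < 0,
                    cell$sweeps$current_step)
    if (length(hyper)) {
      rr <- lapply(hyper, input_resistance)
      r_st <- mean(vapply(rr, `[[`, numeric(1), "r_steady"))
      r_pk <- mean(vapply(rr, `[[`, numeric(1), "r_peak"))
    }
  }
  data.frame(cell_id = cell$cell_id, upper_cutoff = cutoff,
             ap_amplitude = apamp,
             peak_to_sustained_ipsi = pts("ipsi_tone"),
             peak_to_sustained_contra = pts("contra_tone"),
             sustained_hyperpol = sus_hyp,
             r_in_steady = r_st, r_in_peak = r_pk,
             stringsAsFactors = FALSE)
}

#' Feature table for a cohort
#'
#' @param cohort list of `list(cell=, truth=)` as returned by
#'   [gen_cohort()], or a list of `lso_cell`s.
#' @return data.frame of per-cell features (see [extract_features()]), with
#'   a `true_class` column when ground truth is available.
#' @export
cohort_features <- function(cohort) {
  rows <- lapply(cohort, function(el) {
    cell <- if (inherits(el, "lso_cell")) el else el$cell
    f <- extract_features(cell)
    f$true_class <- if (!inherits(el, "lso_cell") && !is.null(el$truth))
      el$truth$class_label else NA_character_
    f
  })
  do.call(rbind, rows)
}

#' Classify cells from (upper cutoff, AP amplitude)
#'
#' Feature space is `(log10 upper cutoff, AP amplitude)`, z-scored. With
#' `anchors` (a character vector of known labels, `NA` for unlabeled cells)
#' the centroids are defined by the labeled cells and every cell is
#' assigned to the nearest centroid — the procedure used when a subset of
#' recordings has anatomical confirmation. Without anchors, 2-means with
#' deterministic farthest-pair initialization is used and the cluster with
#' the higher mean cutoff is labeled `"principal"`. The confidence is a
#' silhouette-style score `(d2 - d1)/max(d1, d2)` from the distances to the
#' two centroids.
#'
#' @param features data.frame with `upper_cutoff` and `ap_amplitude`.
#' @param anchors optional character vector (length `nrow(features)`) with
#'   entries `"principal"`, `"non_principal"` or `NA`.
#' @return data.frame with `label` and `confidence`; cells are marked
#'   `"unassignable"` when a 2-group solution is not identifiable.
#' @export
cluster_cells <- function(features, anchors = NULL) {
  stopifnot(is.data.frame(features),
            all(c("upper_cutoff", "ap_amplitude") %in% names(features)))
  X <- cbind(log10(features$upper_cutoff), features$ap_amplitude)
  complete <- stats::complete.cases(X)
  if (!any(complete)) stop("no cells with complete features")
  if (sum(complete) < 4) {
    # a 2-group solution is not identifiable from so few cells
    return(data.frame(cell_id = if (!is.null(features$cell_id))
      features$cell_id else seq_len(nrow(features)),
      label = "unassignable", confidence = NA_real_,
      stringsAsFactors = FALSE))
  }
  Z <- scale(X[complete, , drop = FALSE])
  # a constant feature (zero variance) carries no information; drop its scale
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  n <- nrow(Z)
  labels <- rep(NA_character_, nrow(features))
  conf <- rep(NA_real_, nrow(features))
  if (!is.null(anchors)) {
    stopifnot(length(anchors) == nrow(features))
    anc <- anchors[complete]
    cen <- rbind(colMeans(Z[which(anc == "principal"), , drop = FALSE]),
                 colMeans(Z[which(anc == "non_principal"), , drop = FALSE]))
    if (any(!is.finite(cen)))
      stop("anchors must include both classes")
    cls_names <- c("principal", "non_principal")
  } else {
    if (n < 4) stop("need >= 4 cells for unsupervised clustering")
    # farthest pair as initial centers: deterministic
    D <- as.matrix(stats::dist(Z))
    ij <- which(D == max(D), arr.ind = TRUE)[1, ]
    km <- stats::kmeans(Z, centers = Z[c(ij[1], ij[2]), , drop = FALSE],
                        iter.max = 100)
    cen <- km$centers
    # higher mean cutoff (first, log-cutoff z column) = principal
    cls_names <- if (cen[1, 1] >= cen[2, 1])
      c("principal", "non_principal") else c("non_principal", "principal")
  }
  d1 <- sqrt(rowSums((Z - matrix(cen[1, ], n, 2, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((Z - matrix(cen[2, ], n, 2, byrow = TRUE))^2))
  assign <- ifelse(d1 <= d2, cls_names[1], cls_names[2])
  cf <- abs(d2 - d1) / pmax(pmax(d1, d2), .Machine$double.eps)
  labels[complete] <- assign
  conf[complete] <- cf
  data.frame(cell_id = if (!is.null(features$cell_id)) features$cell_id
             else seq_len(nrow(features)),
             label = labels, confidence = conf, stringsAsFactors = FALSE)
}

#' Group summary (n, mean, SEM)
#'
#' @param x numeric sample (n >= 2) — or pass `n`, `mean`, `sem` directly.
#' @param n,mean,sem printed summary values, used when `x` is missing.
#' @return an `lso_group`: list with `n`, `mean`, `sem`, `sd`
#'   (`sd = sem * sqrt(n)`).
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sem = NULL) {
  if (!is.null(x)) {
    x <- x[is.finite(x)]
    if (length(x) < 2) stop("group needs n >= 2")
    n <- length(x); mean <- base::mean(x)
    sem <- stats::sd(x) / sqrt(n)
  }
  if (is.null(n) || is.null(mean) || is.null(sem))
    stop("provide either a sample or (n, mean, sem)")
  if (n < 2) stop("group needs n >= 2")
  if (sem <= 0) stop("sem must be positive")
  structure(list(n = n, mean = mean, sem = sem, sd = sem * sqrt(n)),
            class = "lso_group")
}

#' Pooled-variance two-sample t test from group summaries
#'
#' Student's t with pooled variance computed from means, SEMs and group
#' sizes (`sd_i = sem_i * sqrt(n_i)`, `df = n_a + n_b - 2`), two-tailed p.
#' Set `welch = TRUE` for the Welch variant.
#'
#' @param a,b `lso_group` summaries.
#' @param welch use Welch's unequal-variance form instead of pooling.
#' @return list with `statistic`, `df`, `p_two_tailed`.
#' @export
pooled_t_from_summaries <- function(a, b, welch = FALSE) {
  stopifnot(inherits(a, "lso_group"), inherits(b, "lso_group"))
  va <- a$sd^2; vb <- b$sd^2
  if (isTRUE(welch)) {
    se2 <- va / a$n + vb / b$n
    df <- se2^2 / ((va / a$n)^2 / (a$n - 1) + (vb / b$n)^2 / (b$n - 1))
    t <- (a$mean - b$mean) / sqrt(se2)
  } else {
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / (a$n + b$n - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    df <- a$n + b$n - 2
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  list(statistic = t, df = df, p_two_tailed = 2 * stats::pt(-abs(t), df))
}

#' Hedges' g from group summaries
#'
#' Standardized mean difference with the (n-1)-weighted pooled SD. The
#' uncorrected convention is the default; `correct = TRUE` applies the
#' small-sample J factor.
#'
#' @param a,b `lso_group` summaries.
#' @param correct apply the small-sample correction `J = 1 - 3/(4*df - 1)`.
#' @return effect size (sign follows `mean_a - mean_b`).
#' @export
hedges_g <- function(a, b, correct = FALSE) {
  stopifnot(inherits(a, "lso_group"), inherits(b, "lso_group"))
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0) stop("zero pooled SD")
  g <- (a$mean - b$mean) / sqrt(sp2)
  if (isTRUE(correct)) {
    df <- a$n + b$n - 2
    g <- g * (1 - 3 / (4 * df - 1))
  }
  g
}

#' Pearson correlation with two-tailed p
#'
#' Sample correlation; p from `t = r*sqrt((n-2)/(1-r^2))` on `n - 2` df.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `r`, `statistic` (t), `df`, `p_two_tailed`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, statistic = t, df = n - 2,
       p_two_tailed = 2 * stats::pt(-abs(t), n - 2))
}
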