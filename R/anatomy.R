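#' Construct a centerline map
#'
#' The LSO centerline as a 2D polyline (section coordinates, um), drawn from
#' the lateral-most to the medial-most point of the nucleus.
#'
#' @param vertices numeric matrix (>= 2 rows, 2 columns) of polyline
#'   vertices, lateral end first.
#' @return an `lso_centerline` with `vertices` and `arc_length` (um).
#' @export
centerline_map <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2 || ncol(vertices) != 2)
    stop("centerline needs >= 2 vertices with 2 coordinates")
  seg <- sqrt(rowSums(diff(vertices)^2))
  if (sum(seg) <= 0) stop("degenerate centerline: zero arc length")
  structure(list(vertices = vertices, seg_lengths = seg,
                 arc_length = sum(seg)),
            class = "lso_centerline")
}

#' Normalized lateromedial position of a soma
#'
#' Projects the soma onto the nearest point of the centerline polyline
#' (per-segment orthogonal projection, clamped to segment ends; ties at
#' polyline corners resolve toward the smaller arc length) and returns its
#' arc-length fraction from the lateral end (0 = lateral, 1 = medial).
#'
#' @param centerline an `lso_centerline`.
#' @param soma_xy numeric length-2 soma coordinates (same units).
#' @return fraction in \[0, 1\].
#' @export
normalized_position <- function(centerline, soma_xy) {
  stopifnot(inherits(centerline, "lso_centerline"), length(soma_xy) == 2)
  V <- centerline$vertices
  # sanity bound: reject somata absurdly far from the nucleus
  dmin0 <- min(sqrt(colSums((t(V) - soma_xy)^2)))
  if (dmin0 > 2 * centerline$arc_length)
    stop("soma is further than 2x the arc length from the centerline")
  cum <- c(0, cumsum(centerline$seg_lengths))
  best_d2 <- Inf; best_s <- 0
  for (i in seq_len(nrow(V) - 1)) {
    a <- V[i, ]; b <- V[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else
      min(max(sum((soma_xy - a) * ab) / len2, 0), 1)
    p <- a + t * ab
    d2 <- sum((soma_xy - p)^2)
    s <- cum[i] + t * sqrt(len2)
    if (d2 < best_d2 - 1e-12 ||
        (abs(d2 - best_d2) <= 1e-12 && s < best_s)) {
      best_d2 <- d2; best_s <- s
    }
  }
  best_s / centerline$arc_length
}

#' Somatic synaptic coverage percentage
#'
#' Per EM section, coverage is 100 x (sum of apposition lengths) / (soma
#' perimeter length); the mean over sections is returned. Measurements from
#' fewer than three sections are flagged invalid (but still computed).
#'
#' @param perimeters numeric vector of per-section soma perimeter lengths
#'   (um), positive.
#' @param appositions list (one element per section) of apposition-length
#'   vectors (um).
#' @return list with `coverage_percent`, `per_section`, `n_sections`,
#'   `valid` (n_sections >= 3).
#' @export
coverage_percent <- function(perimeters, appositions) {
  if (!length(perimeters)) stop("need at least one section")
  if (length(appositions) != length(perimeters))
    stop("one apposition vector per section required")
  if (any(perimeters <= 0)) stop("perimeters must be positive")
  per_sec <- vapply(seq_along(perimeters), function(i) {
    s <- sum(appositions[[i]])
    if (s > perimeters[i])
      stop(sprintf("section %d: apposition sum (%.1f) exceeds perimeter (%.1f)",
                   i, s, perimeters[i]))
    100 * s / perimeters[i]
  }, numeric(1))
  list(coverage_percent = mean(per_sec), per_section = per_sec,
       n_sections = length(per_sec), valid = length(per_sec) >= 3)
}

# Spearman rho on ranks (average ranks for ties).
spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))

#' Tonotopy statistic: CF/BF versus lateromedial position
#'
#' Spearman rank correlation of frequency against normalized position with
#' a two-tailed p value: exact permutation enumeration for n <= 10,
#' t approximation above.
#'
#' @param positions normalized positions (>= 5 cells).
#' @param frequencies CF or BF (Hz), same length.
#' @return list with `rho`, `p_two_tailed`, `n`, `method`.
#' @export
tonotopy_stat <- function(positions, frequencies) {
  ok <- is.finite(positions) & is.finite(frequencies)
  x <- positions[ok]; y <- frequencies[ok]
  n <- length(x)
  if (n < 5) stop("need >= 5 cells with both position and frequency")
  if (length(unique(x)) == 1) stop("all positions tied: rank correlation undefined")
  rho <- spearman_rho(x, y)
  if (n <= 10) {
    rx <- rank(x); ry <- rank(y)
    perms <- permutations_all(n)
    # rho under permutation depends only on the cross sum of ranks
    s <- c(matrix(rx[perms], nrow(perms), n) %*% ry)
    rhos <- (s - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p_val <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p_val <- 2 * stats::pt(-abs(t), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_two_tailed = p_val, n = n, method = method)
}

# All permutations of 1..n as an (n! x n) matrix, built block-wise so the
# enumeration stays vectorized; n <= 10 bounds the size.
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  blocks <- lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  })
  do.call(rbind, blocks)
}
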