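#' Compositional and diversity metrics
#'
#' Shared statistics for comparing community compositions: Bray-Curtis
#' dissimilarity, Kullback-Leibler and Jensen-Shannon divergences, Shannon
#' diversity, the inverse cumulative species-abundance distribution (SAD),
#' and its power-law slope. All entropies use the natural logarithm; only
#' [power_law_slope()] works in log10, as is conventional for SAD plots.
#'
#' @name metrics
NULL

check_composition <- function(p, tol = 1e-8, arg = "p") {
  if (!is.numeric(p)) stop(arg, " must be numeric", call. = FALSE)
  if (any(p < 0)) stop(arg, " has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(arg, " does not sum to 1 (sum = ", format(sum(p)), ")", call. = FALSE)
  }
  invisible(p)
}

#' Bray-Curtis dissimilarity between two compositions
#'
#' For relative-abundance vectors (each summing to 1) the Bray-Curtis
#' dissimilarity reduces to half the L1 distance: \eqn{\frac{1}{2}\sum_i |p_i - q_i|}.
#' Returns 0 for identical compositions and 1 for disjoint supports.
#'
#' @param p,q numeric composition vectors of equal length (nonnegative,
#'   summing to 1).
#' @return a number in \[0, 1\].
#' @export
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) {
    stop("length mismatch: ", length(p), " vs ", length(q), call. = FALSE)
  }
  sum(abs(p - q)) / sum(p + q)
}

# Row-wise Bray-Curtis between matching rows of two S x O matrices.
bray_curtis_rows <- function(P, Q) {
  rowSums(abs(P - Q)) / rowSums(P + Q)
}

# Full pairwise Bray-Curtis among rows of a composition matrix.
bray_curtis_matrix <- function(P) {
  as.matrix(stats::dist(P, method = "manhattan")) / 2
}

#' Kullback-Leibler divergence with the 0 log 0 = 0 convention
#'
#' @param p,q composition vectors; `q` must be strictly positive wherever
#'   `p > 0`.
#' @return nonnegative KL divergence \eqn{\sum_i p_i \log(p_i / q_i)}
#'   (natural log).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop("length mismatch: ", length(p), " vs ", length(q), call. = FALSE)
  }
  pos <- p > 0
  bad <- pos & q <= 0
  if (any(bad)) {
    stop("KL undefined: q is zero where p > 0 at index ", which(bad)[1],
         call. = FALSE)
  }
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' KL, symmetric KL, and Jensen-Shannon distance
#'
#' Computes `KL(p||q)`, the symmetric KL divergence
#' `KL(p||q) + KL(q||p)`, and the Jensen-Shannon distance (the square root
#' of the Jensen-Shannon divergence, natural log, so the distance is
#' bounded by `sqrt(log 2)`). The JS distance is always defined; the KL
#' components are `Inf`-free only when supports are compatible, and a
#' support violation raises an error naming the offending index.
#'
#' The reverse direction `KL(q||p)` used by the symmetric form is
#' reported as `Inf` when `p` lacks support where `q` has mass.
#'
#' @inheritParams kl_divergence
#' @return list with elements `kl`, `symmetric_kl`, `jsd`.
#' @export
kl_and_jsd <- function(p, q) {
  jsd <- js_distance(p, q)
  kl_pq <- kl_divergence(p, q)
  kl_qp <- tryCatch(kl_divergence(q, p), error = function(e) Inf)
  list(kl = kl_pq, symmetric_kl = kl_pq + kl_qp, jsd = jsd)
}

#' Jensen-Shannon distance
#'
#' @inheritParams kl_divergence
#' @return `sqrt(0.5 KL(p||m) + 0.5 KL(q||m))` with `m = (p + q)/2`.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop("length mismatch: ", length(p), " vs ", length(q), call. = FALSE)
  }
  m <- (p + q) / 2
  # m > 0 wherever p > 0 or q > 0, so both KL terms are finite
  sqrt(0.5 * kl_divergence(p, m) + 0.5 * kl_divergence(q, m))
}

# Row-wise JSD between matching rows of two matrices.
js_distance_rows <- function(P, Q) {
  vapply(seq_len(nrow(P)), function(s) js_distance(P[s, ], Q[s, ]), numeric(1))
}

#' Shannon diversity of a composition
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with `0 ln 0 := 0`. Natural log, so the
#' uniform composition over O taxa scores `log(O)`.
#'
#' @param p composition vector.
#' @return nonnegative diversity.
#' @export
shannon_diversity <- function(p) {
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Inverse cumulative species-abundance distribution
#'
#' Pools all sample-by-taxon relative abundances of a table and evaluates
#' the empirical survival function `P(abundance > a)` on a grid. Zero
#' entries are included in the pool, so the curve at `a = 0` equals the
#' fraction of strictly positive entries.
#'
#' @param table an [abundance_table()] (or plain relative-abundance matrix).
#' @param grid increasing numeric vector of abundance thresholds.
#' @return data.frame with columns `abundance` and `survival`.
#' @export
inverse_cdf_sad <- function(table, grid) {
  x <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  pool <- as.numeric(x)
  n <- length(pool)
  surv <- vapply(grid, function(a) sum(pool > a) / n, numeric(1))
  data.frame(abundance = grid, survival = surv)
}

#' Power-law slope of a survival curve
#'
#' Least-squares slope of `log10(survival)` against `log10(abundance)`
#' restricted to abundances in `[range_lo, range_hi]` (defaults
#' `1e-3`–`1e-1`, the scaling window typical of gut species-abundance
#' distributions). Points with zero survival are dropped.
#'
#' @param curve data.frame as returned by [inverse_cdf_sad()].
#' @param range_lo,range_hi abundance window for the fit.
#' @return the fitted slope (typically negative).
#' @export
power_law_slope <- function(curve, range_lo = 1e-3, range_hi = 1e-1) {
  keep <- curve$abundance >= range_lo & curve$abundance <= range_hi &
    curve$survival > 0 & curve$abundance > 0
  if (sum(keep) < 3) {
    stop("fewer than 3 usable curve points in [", range_lo, ", ", range_hi, "]",
         call. = FALSE)
  }
  lx <- log10(curve$abundance[keep])
  ly <- log10(curve$survival[keep])
  unname(stats::coef(stats::lm(ly ~ lx))[2])
}

#' Per-taxon moments of an abundance table
#'
#' Sample mean, standard deviation, and the pairwise abundance covariance
#' \eqn{\langle \delta x_i \delta x_j \rangle} across samples (denominator
#' S - 1).
#'
#' @param table an [abundance_table()] or relative-abundance matrix
#'   (samples in rows).
#' @return list with `mean` (length O), `sd` (length O), `cov` (O x O).
#' @export
abundance_moments <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 samples for SD/covariance", call. = FALSE)
  cv <- stats::cov(x)
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd), cov = cv)
}
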