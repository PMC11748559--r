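#' Gaussian-mixture model of the latent space
#'
#' The fitted latent coordinates of a cohort are summarized by a finite
#' Gaussian mixture `p0(z)` with full covariances. Because EM converges
#' to local optima, fitting runs many seeded restarts for each component
#' count (1 to `max_components`) and keeps the model with the lowest
#' Bayesian information criterion overall; BIC ties break toward fewer
#' components. `p0(z)` is the generative engine: sampling it and pushing
#' draws through [compose()] yields in-silico cohorts.
#'
#' @name latent-gmm
NULL

# Log-density of rows of Z under N(mu, Sigma), via Cholesky.
dmvnorm_log <- function(Z, mu, Sigma) {
  Kd <- ncol(Z)
  ch <- chol(Sigma)
  centered <- sweep(Z, 2, mu)
  # solve t(ch) y = t(centered): Mahalanobis via triangular solve
  y <- backsolve(ch, t(centered), transpose = TRUE)
  maha <- colSums(y^2)
  -0.5 * (Kd * log(2 * pi) + 2 * sum(log(diag(ch))) + maha)
}

# Floor the eigenvalues of a covariance matrix at `floor_ev`. The cheap
# path just symmetrizes and checks positive-definiteness via Cholesky;
# the eigenvalue floor is applied only when that fails.
regularize_cov <- function(Sigma, floor_ev = 1e-6) {
  Sigma <- (Sigma + t(Sigma)) / 2
  ok <- tryCatch({ chol(Sigma - diag(floor_ev * 0.999, nrow(Sigma))); TRUE },
                 error = function(e) FALSE)
  if (ok) return(Sigma)
  eg <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(eg$values, floor_ev)
  eg$vectors %*% (vals * t(eg$vectors))
}

logsumexp_rows <- function(A) {
  m <- row_max(A)
  m + log(rowSums(exp(A - m)))
}

em_gmm_once <- function(Z, ncomp, floor_ev = 1e-6, tol = 1e-7, max_iter = 200L) {
  S <- nrow(Z); Kd <- ncol(Z)
  # init: random distinct rows as means, pooled covariance, uniform weights
  mu <- Z[sample.int(S, ncomp), , drop = FALSE]
  pooled <- regularize_cov(stats::cov(Z) + diag(1e-8, Kd), floor_ev)
  covs <- replicate(ncomp, pooled, simplify = FALSE)
  w <- rep(1 / ncomp, ncomp)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logdens <- vapply(seq_len(ncomp),
                      function(j) dmvnorm_log(Z, mu[j, ], covs[[j]]),
                      numeric(S))
    logdens <- matrix(logdens, S, ncomp)
    logw <- sweep(logdens, 2, log(w), "+")
    lse <- logsumexp_rows(logw)
    ll <- sum(lse)
    resp <- exp(logw - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)       # collapsed component
    w <- nk / S
    for (j in seq_len(ncomp)) {
      mu[j, ] <- colSums(resp[, j] * Z) / nk[j]
      centered <- sweep(Z, 2, mu[j, ])
      covs[[j]] <- regularize_cov(
        crossprod(centered * sqrt(resp[, j])) / nk[j], floor_ev)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(weights = w, means = mu, covs = covs, loglik = ll)
}

#' Fit a BIC-selected Gaussian mixture to latent coordinates
#'
#' For each component count `1..max_components`, runs `restarts` seeded
#' EM fits with full covariances (eigenvalue floor `floor_ev`) and keeps
#' the model minimizing `BIC = -2 loglik + df log(S)` across all fits,
#' with ties broken toward fewer components.
#'
#' @param Z S x K matrix of latent coordinates (or a `crl_fit`, whose `Z`
#'   is used).
#' @param max_components largest mixture size tried (default 5).
#' @param restarts seeded EM restarts per component count (default 100).
#' @param seed master RNG seed; each restart derives its own stream.
#' @param floor_ev eigenvalue floor applied to every covariance
#'   (default 1e-6), engaged with a warning when `S <= K`.
#' @return object of class `latent_gmm`: `n_components`, `weights`,
#'   `means` (ncomp x K), `covariances` (list of K x K), `bic`, `loglik`,
#'   `n_restarts_used`, `K`.
#' @export
fit_latent_gmm <- function(Z, max_components = 5L, restarts = 100L,
                           seed = 1L, floor_ev = 1e-6) {
  if (inherits(Z, "crl_fit")) Z <- Z$Z
  Z <- as.matrix(Z)
  S <- nrow(Z); Kd <- ncol(Z)
  if (S < 2) stop("need at least 2 samples to fit a mixture", call. = FALSE)
  if (S <= Kd) {
    warning("S <= K: covariance eigenvalue floor ", floor_ev, " engaged",
            call. = FALSE)
  }
  best <- NULL
  for (ncomp in seq_len(max_components)) {
    df <- (ncomp - 1) + ncomp * Kd + ncomp * Kd * (Kd + 1) / 2
    for (r in seq_len(restarts)) {
      fit <- withr_seed(seed + 7919L * ncomp + r,
                        tryCatch(em_gmm_once(Z, ncomp, floor_ev),
                                 error = function(e) NULL))
      if (is.null(fit)) next
      bic <- -2 * fit$loglik + df * log(S)
      # strict < keeps the smaller-ncomp model on ties (loop is ascending)
      if (is.null(best) || bic < best$bic - 1e-9) {
        best <- list(n_components = ncomp, weights = fit$weights,
                     means = fit$means, covariances = fit$covs,
                     bic = bic, loglik = fit$loglik)
      }
    }
  }
  if (is.null(best)) stop("all EM restarts failed", call. = FALSE)
  best$n_restarts_used <- as.integer(restarts)
  best$K <- Kd
  class(best) <- "latent_gmm"
  best
}

#' @export
print.latent_gmm <- function(x, ...) {
  cat("latent_gmm: ", x$n_components, " component(s) in K = ", x$K,
      " dims; BIC = ", format(x$bic, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Per-sample log-likelihood under the latent mixture
#'
#' @param dist a `latent_gmm`.
#' @param Z matrix of latent coordinates (rows = samples) or a single
#'   K-vector.
#' @return numeric vector of log-densities.
#' @export
latent_log_likelihood <- function(dist, Z) {
  stopifnot(inherits(dist, "latent_gmm"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != dist$K) {
    stop("latent dimension mismatch: points have ", ncol(Z),
         " dims, mixture has ", dist$K, call. = FALSE)
  }
  S <- nrow(Z)
  logdens <- vapply(seq_len(dist$n_components),
                    function(j) dmvnorm_log(Z, dist$means[j, ],
                                            dist$covariances[[j]]),
                    numeric(S))
  logdens <- matrix(logdens, S, dist$n_components)
  logsumexp_rows(sweep(logdens, 2, log(dist$weights), "+"))
}

#' Draw latent coordinates from the mixture
#'
#' @param dist a `latent_gmm`.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return n x K matrix.
#' @export
sample_latent <- function(dist, n, seed = 1L) {
  stopifnot(inherits(dist, "latent_gmm"))
  withr_seed(seed, {
    comp <- sample.int(dist$n_components, n, replace = TRUE,
                       prob = dist$weights)
    Z <- matrix(0, n, dist$K)
    for (j in seq_len(dist$n_components)) {
      idx <- which(comp == j)
      if (!length(idx)) next
      ch <- chol(dist$covariances[[j]])
      G <- matrix(stats::rnorm(length(idx) * dist$K), length(idx), dist$K)
      Z[idx, ] <- sweep(G %*% ch, 2, dist$means[j, ], "+")
    }
    Z
  })
}

#' Sample an in-silico cohort from the generative model
#'
#' Draws latent coordinates from `p0(z)`, composes relative abundances
#' with the universal preferences, optionally adds multinomial read
#' sampling at a given depth, and — when loadings are present — emits
#' phenotypes `Z L` mapped back to original units via the stored
#' z-scoring parameters (noiseless by default; supply `residual_sd`, a
#' per-phenotype SD in z-score units, to add Gaussian observation noise).
#'
#' @param dist a `latent_gmm`.
#' @param Theta K x O preference matrix (or a `crl_fit`, supplying
#'   `Theta`, `L` and the phenotype scaler).
#' @param n cohort size.
#' @param seed RNG seed.
#' @param L optional K x P loading matrix.
#' @param scaler optional list(center, scale, phenotype_ids) for mapping
#'   phenotypes to original units.
#' @param depth optional multinomial read depth per sample.
#' @param residual_sd optional per-phenotype Gaussian noise SD (z-score
#'   units), recycled over phenotypes.
#' @return object of class `generated_cohort`: `Z` (n x K),
#'   `compositions` (n x O, rows sum to 1), `counts` (n x O or NULL),
#'   `phenotypes` (n x P in original units, or NULL),
#'   `phenotypes_z` (z-score units, or NULL), `seed`.
#' @export
sample_cohort <- function(dist, Theta, n, seed = 1L, L = NULL, scaler = NULL,
                          depth = NULL, residual_sd = NULL) {
  if (inherits(Theta, "crl_fit")) {
    fit <- Theta
    Theta <- fit$Theta
    if (is.null(L)) L <- fit$L
    if (is.null(scaler)) scaler <- fit$scaler
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  Z <- sample_latent(dist, n, seed)
  Q <- compose(Z, Theta)
  counts <- NULL
  if (!is.null(depth)) {
    counts <- withr_seed(seed + 1L, t(vapply(seq_len(n), function(s) {
      as.numeric(stats::rmultinom(1, depth, Q[s, ]))
    }, numeric(ncol(Q)))))
    colnames(counts) <- colnames(Q)
  }
  phen <- phen_z <- NULL
  if (!is.null(L)) {
    phen_z <- Z %*% L
    if (!is.null(residual_sd)) {
      sds <- rep_len(residual_sd, ncol(phen_z))
      noise <- withr_seed(seed + 2L,
        matrix(stats::rnorm(n * ncol(phen_z)), n) %*% diag(sds, ncol(phen_z)))
      phen_z <- phen_z + noise
    }
    phen <- if (!is.null(scaler)) {
      inverse_zscore(phen_z, scaler$center, scaler$scale)
    } else phen_z
    if (!is.null(scaler$phenotype_ids)) {
      colnames(phen) <- colnames(phen_z) <- scaler$phenotype_ids
    } else if (!is.null(colnames(L))) {
      colnames(phen) <- colnames(phen_z) <- colnames(L)
    }
  }
  structure(list(Z = Z, compositions = Q, counts = counts,
                 phenotypes = phen, phenotypes_z = phen_z,
                 seed = as.integer(seed)),
            class = "generated_cohort")
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat("generated_cohort: ", nrow(x$compositions), " samples x ",
      ncol(x$compositions), " taxa",
      if (!is.null(x$phenotypes)) paste0(", ", ncol(x$phenotypes), " phenotypes"),
      if (!is.null(x$counts)) " (+ counts)", "\n", sep = "")
  invisible(x)
}

#' Diagnostics comparing a generated cohort with reference data
#'
#' Computes the statistics used to judge whether a generative model
#' reproduces a real cohort: per-taxon mean and SD (reference vs
#' generated), pairwise abundance covariances, Shannon-diversity
#' distributions, Bray-Curtis dissimilarities for random pairs and for
#' nearest-neighbor pairs (each sample against its closest non-self
#' partner), and the inverse cumulative species-abundance distribution
#' with its power-law slope on the standard window.
#'
#' @param real an [abundance_table()] (or relative matrix) of reference
#'   samples.
#' @param generated a `generated_cohort` or relative-abundance matrix
#'   with the same taxa.
#' @param n_pairs random pairs used for the Bray-Curtis distributions.
#' @param seed RNG seed for pair sampling.
#' @param sad_grid abundance grid for the survival curves.
#' @return object of class `cohort_diagnostics` (a list of tables),
#'   writable with [write_diagnostics()].
#' @export
generative_diagnostics <- function(real, generated, n_pairs = 2000L,
                                   seed = 1L,
                                   sad_grid = 10^seq(-4, 0, length.out = 60)) {
  Xr <- composition_values(real)
  Xg <- if (inherits(generated, "generated_cohort")) {
    generated$compositions
  } else as.matrix(generated)
  if (ncol(Xr) != ncol(Xg)) {
    stop("taxon count mismatch: ", ncol(Xr), " vs ", ncol(Xg), call. = FALSE)
  }
  if (!is.null(colnames(Xr)) && !is.null(colnames(Xg))) {
    if (!setequal(colnames(Xr), colnames(Xg))) {
      stop("taxa mismatch between real and generated tables", call. = FALSE)
    }
    Xg <- Xg[, colnames(Xr), drop = FALSE]
  }
  if (nrow(Xr) < 2 || nrow(Xg) < 2) {
    stop("need at least 2 samples on each side", call. = FALSE)
  }
  mom_r <- abundance_moments(Xr)
  mom_g <- abundance_moments(Xg)

  bc_pairs <- function(X) {
    n <- nrow(X)
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    ok <- i != j
    bray_curtis_rows(X[i[ok], , drop = FALSE], X[j[ok], , drop = FALSE])
  }
  nn_bc <- function(X) {
    D <- bray_curtis_matrix(X)
    diag(D) <- Inf
    apply(D, 1, min)
  }
  withr_seed(seed, {
    bc_rand_r <- bc_pairs(Xr)
    bc_rand_g <- bc_pairs(Xg)
  })

  curve_r <- inverse_cdf_sad(Xr, sad_grid)
  curve_g <- inverse_cdf_sad(Xg, sad_grid)
  slope_r <- tryCatch(power_law_slope(curve_r), error = function(e) NA_real_)
  slope_g <- tryCatch(power_law_slope(curve_g), error = function(e) NA_real_)

  structure(list(
    taxa = colnames(Xr),
    moments = data.frame(taxon = if (is.null(colnames(Xr)))
                           paste0("taxon", seq_len(ncol(Xr))) else colnames(Xr),
                         mean_real = mom_r$mean, mean_generated = mom_g$mean,
                         sd_real = mom_r$sd, sd_generated = mom_g$sd),
    cov_real = mom_r$cov, cov_generated = mom_g$cov,
    shannon_real = apply(Xr, 1, shannon_diversity),
    shannon_generated = apply(Xg, 1, shannon_diversity),
    bc_random_real = bc_rand_r, bc_random_generated = bc_rand_g,
    bc_nearest_real = nn_bc(Xr), bc_nearest_generated = nn_bc(Xg),
    sad_real = curve_r, sad_generated = curve_g,
    sad_slope_real = slope_r, sad_slope_generated = slope_g
  ), class = "cohort_diagnostics")
}

#' @export
print.cohort_diagnostics <- function(x, ...) {
  mr <- x$moments
  cat("cohort_diagnostics over ", nrow(mr), " taxa\n",
      "  mean-abundance correlation (real vs generated): ",
      format(stats::cor(mr$mean_real, mr$mean_generated), digits = 4), "\n",
      "  SAD power-law slope: real ", format(x$sad_slope_real, digits = 4),
      ", generated ", format(x$sad_slope_generated, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Write / read a diagnostics report
#'
#' Serializes a `cohort_diagnostics` object to JSON; reading it back
#' reproduces every numeric field exactly (full-precision encoding).
#'
#' @param x a `cohort_diagnostics`.
#' @param path output file.
#' @return `read_diagnostics()` returns the restored object.
#' @export
write_diagnostics <- function(x, path) {
  stopifnot(inherits(x, "cohort_diagnostics"))
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_diagnostics
#' @export
read_diagnostics <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$moments <- as.data.frame(raw$moments)
  raw$sad_real <- as.data.frame(raw$sad_real)
  raw$sad_generated <- as.data.frame(raw$sad_generated)
  raw$cov_real <- as.matrix(raw$cov_real)
  raw$cov_generated <- as.matrix(raw$cov_generated)
  structure(raw, class = "cohort_diagnostics")
}
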