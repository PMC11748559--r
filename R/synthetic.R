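#' Ground-truth synthetic data
#'
#' Two complementary generators make every stage of the pipeline testable
#' without external data. `simulate_cr()` integrates the raw
#' consumer/resource ODEs — the mechanistic world the latent model
#' coarse-grains — so that fits can be checked against data the model
#' class did not literally generate. `model_based_cohort()` draws data
#' exactly from the model class (low-rank log-linear compositions with
#' optional multinomial sampling noise and linearly latent-coupled
#' phenotypes) for parameter-recovery tests with known truth.
#'
#' @name synthetic-data
NULL

#' Consumer/resource simulation parameters
#'
#' Defines the ODE world
#' \deqn{\frac{1}{n_o}\frac{dn_o}{dt} = \sum_k r_k \theta_{ko} - \delta_o,
#'       \qquad
#'       \frac{dr_k}{dt} = J_k - r_k \sum_o n_o \theta_{ko} \gamma_{ko},}
#' with `O` consumer species, `K` resources, preferences `theta >= 0`,
#' consumption efficiencies `gamma_eff > 0`, death/dilution rates
#' `delta >= 0`, and resource inflows `J_k` (constants or a function of
#' time returning a K-vector).
#'
#' @param theta K x O nonnegative preference matrix.
#' @param gamma_eff K x O positive consumption efficiencies.
#' @param delta length-O nonnegative death/dilution rates.
#' @param inflow length-K nonnegative constants, or `function(t)`
#'   returning a K-vector.
#' @param n0 length-O strictly positive initial consumer abundances.
#' @param r0 length-K strictly positive initial resource abundances.
#' @return a `cr_params` list.
#' @export
cr_params <- function(theta, gamma_eff, delta, inflow, n0, r0) {
  theta <- as.matrix(theta); gamma_eff <- as.matrix(gamma_eff)
  K <- nrow(theta); O <- ncol(theta)
  if (!all(dim(gamma_eff) == c(K, O))) {
    stop("gamma_eff must match theta's K x O shape", call. = FALSE)
  }
  if (any(theta < 0) || any(gamma_eff <= 0)) {
    stop("theta must be nonnegative and gamma_eff positive", call. = FALSE)
  }
  if (length(delta) != O || any(delta < 0)) {
    stop("delta must be length O and nonnegative", call. = FALSE)
  }
  if (!is.function(inflow)) {
    if (length(inflow) != K || any(inflow < 0)) {
      stop("inflow must be length K and nonnegative (or a function)", call. = FALSE)
    }
  }
  if (length(n0) != O || any(n0 <= 0)) {
    stop("n0 must be length O and strictly positive", call. = FALSE)
  }
  if (length(r0) != K || any(r0 <= 0)) {
    stop("r0 must be length K and strictly positive", call. = FALSE)
  }
  structure(list(theta = theta, gamma_eff = gamma_eff, delta = delta,
                 inflow = inflow, n0 = n0, r0 = r0, K = K, O = O),
            class = "cr_params")
}

#' Integrate the consumer/resource dynamics
#'
#' Adaptive integration (lsoda) of the C/R ODEs, also accumulating the
#' running integrals `z_k(t) = -integral of r_k` that define the latent
#' variables. Since resources are nonnegative, each `z_k` is monotone
#' non-increasing. Abundances that dip below `-neg_tol` abort with an
#' error (suggesting tighter tolerances); values in `(-neg_tol, 1e-14)`
#' are clamped to 0 at save points.
#'
#' @param params a [cr_params()].
#' @param t_end final time.
#' @param dt_save spacing of saved time points.
#' @param rtol,atol integration tolerances (defaults 1e-8, 1e-10).
#' @param neg_tol negativity tolerance before aborting (default 1e-8).
#' @return a `cr_trajectory`: `times`, `n` (T x O), `r` (T x K), `z`
#'   (T x K, the negative resource integrals).
#' @export
simulate_cr <- function(params, t_end, dt_save, rtol = 1e-8, atol = 1e-10,
                        neg_tol = 1e-8) {
  stopifnot(inherits(params, "cr_params"))
  K <- params$K; O <- params$O
  inflow_fn <- if (is.function(params$inflow)) params$inflow
               else local({ J <- params$inflow; function(t) J })
  deriv <- function(t, y, parms) {
    n <- y[seq_len(O)]
    r <- y[O + seq_len(K)]
    growth <- drop(crossprod(params$theta, r)) - params$delta   # length O
    dn <- n * growth
    consumption <- drop((params$theta * params$gamma_eff) %*% n) # length K
    dr <- inflow_fn(t) - r * consumption
    dz <- -r
    list(c(dn, dr, dz))
  }
  y0 <- c(params$n0, params$r0, rep(0, K))
  times <- seq(0, t_end, by = dt_save)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  sol <- as.matrix(sol)
  state <- sol[, -1, drop = FALSE]
  if (any(state[, seq_len(O + K)] < -neg_tol)) {
    stop("negative abundances beyond tolerance; tighten rtol/atol or reduce ",
         "dt_save (stiff system)", call. = FALSE)
  }
  state[, seq_len(O + K)][state[, seq_len(O + K)] < 1e-14] <- 0
  structure(list(times = sol[, 1],
                 n = state[, seq_len(O), drop = FALSE],
                 r = state[, O + seq_len(K), drop = FALSE],
                 z = state[, O + K + seq_len(K), drop = FALSE]),
            class = "cr_trajectory")
}

#' Cross-sectional snapshot cohort from C/R worlds
#'
#' Simulates one C/R world per host — all sharing the same preference
#' matrix, with host-to-host variation entering through inflows and/or
#' initial conditions — and records each community's relative abundances
#' at `t_snapshot`, optionally with multinomial read sampling.
#'
#' @param params_list list of [cr_params()], one per host, sharing
#'   `theta`.
#' @param t_snapshot sampling time.
#' @param depth optional multinomial read depth; `NULL` returns exact
#'   compositions.
#' @param seed RNG seed for the multinomial draws.
#' @param dt_save internal save spacing (default `t_snapshot / 50`).
#' @return list with `table` (an [abundance_table()]; counts when
#'   `depth` given), `truth` (exact S x O compositions), `Z_cr` (S x K
#'   matrix of latent integrals at the snapshot).
#' @export
snapshot_cohort <- function(params_list, t_snapshot, depth = NULL, seed = 1L,
                            dt_save = t_snapshot / 50) {
  stopifnot(length(params_list) >= 1)
  theta0 <- params_list[[1]]$theta
  for (p in params_list) {
    if (!isTRUE(all.equal(p$theta, theta0))) {
      stop("all hosts must share the same preference matrix", call. = FALSE)
    }
  }
  S <- length(params_list); O <- params_list[[1]]$O; K <- params_list[[1]]$K
  truth <- matrix(0, S, O)
  Zcr <- matrix(0, S, K)
  for (s in seq_len(S)) {
    tr <- simulate_cr(params_list[[s]], t_end = t_snapshot, dt_save = dt_save)
    n_end <- tr$n[nrow(tr$n), ]
    if (all(n_end < 1e-12)) {
      stop("community of host ", s, " went extinct before the snapshot",
           call. = FALSE)
    }
    truth[s, ] <- n_end / sum(n_end)
    Zcr[s, ] <- tr$z[nrow(tr$z), ]
  }
  sample_ids <- paste0("host", seq_len(S))
  taxon_ids <- paste0("taxon", seq_len(O))
  if (is.null(depth)) {
    tab <- abundance_table(truth, sample_ids, taxon_ids, relative = TRUE)
  } else {
    counts <- withr_seed(seed, t(vapply(seq_len(S), function(s) {
      as.numeric(stats::rmultinom(1, depth, truth[s, ]))
    }, numeric(O))))
    tab <- abundance_table(counts, sample_ids, taxon_ids, relative = FALSE)
  }
  dimnames(truth) <- list(sample_ids, taxon_ids)
  list(table = tab, truth = truth, Z_cr = Zcr)
}

#' Build a family of C/R worlds differing only in inflows
#'
#' Convenience generator for [snapshot_cohort()]: draws one shared
#' nonnegative preference matrix and efficiency matrix, then gives each
#' host independently drawn resource inflow rates (log-normal around a
#' common base), which is the canonical way host environments differ in
#' consumer/resource ecology.
#'
#' @param S number of hosts.
#' @param O number of consumer species.
#' @param K number of resources.
#' @param seed RNG seed.
#' @param theta_scale upper bound of the uniform preference draws
#'   (default 1).
#' @param inflow_base mean resource inflow (default 1).
#' @param inflow_sdlog log-SD of per-host inflow variation (default 0.5).
#' @param delta common death rate (default 0.1).
#' @return list of [cr_params()] of length S.
#' @export
cr_world_family <- function(S, O, K, seed = 1L, theta_scale = 1,
                            inflow_base = 1, inflow_sdlog = 0.5,
                            delta = 0.1) {
  withr_seed(seed, {
    theta <- matrix(stats::runif(K * O, 0, theta_scale), K, O)
    gamma_eff <- matrix(stats::runif(K * O, 0.5, 1.5), K, O)
    n0 <- rep(1 / O, O)
    r0 <- rep(1, K)
    lapply(seq_len(S), function(s) {
      J <- stats::rlnorm(K, meanlog = log(inflow_base), sdlog = inflow_sdlog)
      cr_params(theta, gamma_eff, delta = rep(delta, O), inflow = J,
                n0 = n0, r0 = r0)
    })
  })
}

#' Cohort drawn from the model class itself
#'
#' Draws latent coordinates from a Gaussian mixture (default a single
#' standard normal), preferences and loadings from seeded Gaussians,
#' composes abundances, and optionally adds multinomial sampling noise
#' and Gaussian phenotype noise. Returns all ground-truth parameters so
#' recovery can be tested.
#'
#' @param K_true latent dimension of the truth.
#' @param S,O samples and taxa.
#' @param P phenotypes (0 for none).
#' @param seed RNG seed.
#' @param latent_spec optional list(weights, means (ncomp x K), covs
#'   (list)) for a mixture latent distribution; default standard normal.
#' @param theta_scale SD of preference entries (default 1).
#' @param loading_scale SD of loading entries (default 1).
#' @param depth optional multinomial read depth.
#' @param phenotype_sd SD of additive Gaussian noise on phenotypes
#'   (default 0).
#' @return list with `table` ([abundance_table()]), `phenotypes`
#'   ([phenotype_matrix()] or NULL), `truth` (exact compositions), `Z`,
#'   `Theta`, `L`.
#' @export
model_based_cohort <- function(K_true, S, O, P = 0L, seed = 1L,
                               latent_spec = NULL, theta_scale = 1,
                               loading_scale = 1, depth = NULL,
                               phenotype_sd = 0) {
  if (K_true > min(S, O)) {
    stop("K_true must not exceed min(S, O)", call. = FALSE)
  }
  withr_seed(seed, {
    if (is.null(latent_spec)) {
      Z <- matrix(stats::rnorm(S * K_true), S, K_true)
    } else {
      comp <- sample.int(length(latent_spec$weights), S, replace = TRUE,
                         prob = latent_spec$weights)
      Z <- matrix(0, S, K_true)
      for (j in seq_along(latent_spec$weights)) {
        idx <- which(comp == j)
        if (!length(idx)) next
        ch <- chol(latent_spec$covs[[j]])
        G <- matrix(stats::rnorm(length(idx) * K_true), length(idx), K_true)
        Z[idx, ] <- sweep(G %*% ch, 2, latent_spec$means[j, ], "+")
      }
    }
    Theta <- matrix(stats::rnorm(K_true * O, sd = theta_scale), K_true, O)
    L <- if (P > 0) matrix(stats::rnorm(K_true * P, sd = loading_scale),
                           K_true, P) else NULL
    truth <- compose(Z, Theta)
    sample_ids <- paste0("S", seq_len(S))
    taxon_ids <- paste0("taxon", seq_len(O))
    dimnames(truth) <- list(sample_ids, taxon_ids)
    if (is.null(depth)) {
      tab <- abundance_table(truth, sample_ids, taxon_ids, relative = TRUE)
    } else {
      counts <- t(vapply(seq_len(S), function(s) {
        as.numeric(stats::rmultinom(1, depth, truth[s, ]))
      }, numeric(O)))
      tab <- abundance_table(counts, sample_ids, taxon_ids, relative = FALSE)
    }
    phen <- NULL
    if (P > 0) {
      raw <- Z %*% L
      if (phenotype_sd > 0) {
        raw <- raw + matrix(stats::rnorm(S * P, sd = phenotype_sd), S, P)
      }
      colnames(raw) <- paste0("pheno", seq_len(P))
      rownames(raw) <- sample_ids
      phen <- phenotype_matrix(raw)
      colnames(L) <- colnames(raw)
    }
  })
  list(table = tab, phenotypes = phen, truth = truth, Z = Z, Theta = Theta,
       L = L)
}
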