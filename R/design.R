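#' Community design: biased sampling and phenotype-conditioned analysis
#'
#' Once a generative model (latent mixture + preferences + phenotype
#' loadings) is trained, the latent space can be steered toward desired
#' host states: the unbiased log-density `log p0(z)` is amended with a
#' quadratic penalty pulling the model-predicted (z-scored) phenotypes
#' toward target values,
#' \deqn{\log p(z) = \log p_0(z) - \sum_t \gamma\,(\hat m_t(z) - m^*_t)^2,}
#' and the biased distribution is sampled with Metropolis random-walk
#' MCMC started from `p0` draws. Setting `gamma = 0` recovers unbiased
#' sampling; `gamma = 2` gives a strong but not degenerate pull.
#'
#' @name community-design
NULL

#' Bias specification for targeted sampling
#'
#' @param targets named numeric vector: target phenotype values in
#'   z-score units (e.g. `c(starch = 3, pH = 3)` asks for both phenotypes
#'   3 SDs above the cohort mean).
#' @param gamma nonnegative bias strength (default 2).
#' @return a `bias_spec` list.
#' @export
bias_spec <- function(targets, gamma = 2) {
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("targets must be a named numeric vector of phenotype ids", call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  structure(list(targets = targets, gamma = gamma), class = "bias_spec")
}

match_target_cols <- function(L, ids) {
  if (is.null(colnames(L))) {
    stop("loading matrix has no phenotype column names", call. = FALSE)
  }
  idx <- match(ids, colnames(L))
  if (anyNA(idx)) {
    stop("unknown phenotype id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Biased log-density of latent points
#'
#' `log p0(z) - sum_t gamma (z L_t - target_t)^2`, with phenotypes
#' predicted through the linear loadings in z-score units. With
#' `gamma = 0` this equals [latent_log_likelihood()] exactly.
#'
#' @param dist a `latent_gmm`.
#' @param L K x P loading matrix with phenotype column names.
#' @param spec a [bias_spec()].
#' @param Z latent points (matrix rows or single vector).
#' @return numeric vector of unnormalized log-densities.
#' @export
biased_log_density <- function(dist, L, spec, Z) {
  stopifnot(inherits(spec, "bias_spec"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  idx <- match_target_cols(L, names(spec$targets))
  base <- latent_log_likelihood(dist, Z)
  pred <- Z %*% L[, idx, drop = FALSE]
  pen <- rowSums(sweep(pred, 2, spec$targets, "-")^2)
  base - spec$gamma * pen
}

#' MCMC configuration for biased sampling
#'
#' @param n_chains number of independent chains, each started from a
#'   fresh `p0` draw (default 100).
#' @param steps Metropolis steps per chain (default 5000).
#' @param burn_in initial steps discarded (default 1000; must be below
#'   `steps`).
#' @param thin keep every `thin`-th post-burn-in state (default 10).
#' @param proposal_scale SD of the isotropic Gaussian proposal; `NULL`
#'   defaults to a quarter of the mean per-dimension component SD of the
#'   mixture.
#' @param seed RNG seed.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 100L, steps = 5000L, burn_in = 1000L,
                        thin = 10L, proposal_scale = NULL, seed = 1L) {
  if (n_chains < 1 || steps < 1 || burn_in < 0 || thin < 1) {
    stop("chain parameters must be positive", call. = FALSE)
  }
  if (burn_in >= steps) stop("burn_in must be smaller than steps", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), steps = as.integer(steps),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_scale = proposal_scale, seed = as.integer(seed)),
            class = "mcmc_config")
}

default_proposal_scale <- function(dist) {
  sds <- vapply(dist$covariances, function(S) mean(sqrt(diag(S))), numeric(1))
  0.25 * sum(dist$weights * sds)
}

#' Sample the phenotype-biased latent distribution
#'
#' Runs independent Metropolis random-walk chains (symmetric isotropic
#' Gaussian proposals) targeting `exp(biased_log_density)`, each
#' initialized from an unbiased `p0` draw; discards burn-in, thins,
#' pools all chains, and composes microbiomes and phenotypes from the
#' retained latent points. An overall acceptance rate below 1% triggers
#' a warning suggesting a smaller `proposal_scale`.
#'
#' @param dist a `latent_gmm`.
#' @param Theta K x O preference matrix (or a `crl_fit` supplying
#'   `Theta`, `L` and the scaler).
#' @param L K x P loading matrix (required unless supplied via `crl_fit`).
#' @param spec a [bias_spec()].
#' @param mcmc an [mcmc_config()].
#' @param scaler optional phenotype z-scoring parameters for
#'   original-unit output.
#' @return a `generated_cohort` (pooled across chains) with an extra
#'   `acceptance_rate` field.
#' @export
sample_biased <- function(dist, Theta, L = NULL, spec, mcmc = mcmc_config(),
                          scaler = NULL) {
  if (inherits(Theta, "crl_fit")) {
    fit <- Theta
    Theta <- fit$Theta
    if (is.null(L)) L <- fit$L
    if (is.null(scaler)) scaler <- fit$scaler
  }
  if (is.null(L)) stop("loading matrix L is required for biased sampling",
                       call. = FALSE)
  stopifnot(inherits(spec, "bias_spec"), inherits(mcmc, "mcmc_config"))
  Kd <- dist$K
  step_sd <- if (is.null(mcmc$proposal_scale)) default_proposal_scale(dist)
             else mcmc$proposal_scale
  idx <- match_target_cols(L, names(spec$targets))
  Lsub <- L[, idx, drop = FALSE]
  logpost <- function(Zm) {
    pred <- Zm %*% Lsub
    latent_log_likelihood(dist, Zm) -
      spec$gamma * rowSums(sweep(pred, 2, spec$targets, "-")^2)
  }

  starts <- sample_latent(dist, mcmc$n_chains, mcmc$seed)
  n_keep_per <- length(seq.int(mcmc$burn_in + 1L, mcmc$steps, by = mcmc$thin))
  kept <- vector("list", mcmc$n_chains)
  acc <- 0; tot <- 0
  withr_seed(mcmc$seed + 104729L, {
    # all chains advance in lockstep: vectorized proposals and accepts
    cur <- starts
    cur_lp <- logpost(cur)
    keep_at <- seq.int(mcmc$burn_in + 1L, mcmc$steps, by = mcmc$thin)
    buf <- array(NA_real_, c(mcmc$n_chains, Kd, n_keep_per))
    ki <- 0L
    for (t in seq_len(mcmc$steps)) {
      prop <- cur + matrix(stats::rnorm(mcmc$n_chains * Kd, sd = step_sd),
                           mcmc$n_chains, Kd)
      prop_lp <- logpost(prop)
      u <- stats::runif(mcmc$n_chains)
      take <- log(u) < (prop_lp - cur_lp)
      cur[take, ] <- prop[take, , drop = FALSE]
      cur_lp[take] <- prop_lp[take]
      acc <- acc + sum(take); tot <- tot + mcmc$n_chains
      if (ki < n_keep_per && t == keep_at[ki + 1L]) {
        ki <- ki + 1L
        buf[, , ki] <- cur
      }
    }
    kept <- matrix(aperm(buf, c(1, 3, 2)), n_keep_per * mcmc$n_chains, Kd)
  })
  rate <- acc / tot
  if (rate < 0.01) {
    warning("MCMC acceptance rate ", format(rate, digits = 3),
            " < 1%; consider a smaller proposal_scale", call. = FALSE)
  }
  Z <- kept
  Q <- compose(Z, Theta)
  phen_z <- Z %*% L
  phen <- if (!is.null(scaler)) {
    inverse_zscore(phen_z, scaler$center, scaler$scale)
  } else phen_z
  if (!is.null(colnames(L))) colnames(phen) <- colnames(phen_z) <- colnames(L)
  out <- structure(list(Z = Z, compositions = Q, counts = NULL,
                        phenotypes = phen, phenotypes_z = phen_z,
                        seed = mcmc$seed),
                   class = "generated_cohort")
  out$acceptance_rate <- rate
  # pooled rows are ordered with the chain index varying fastest
  out$chain <- rep(seq_len(mcmc$n_chains), n_keep_per)
  out
}

#' Predict a microbiome composition from partial phenotypes
#'
#' Deeply samples the unbiased generative model, retains the draws whose
#' model-predicted phenotypes fall within `tolerance` (in SD / z-score
#' units, default 0.2) of every constrained value, and returns the mean
#' retained composition (renormalized) — the model's best guess of the
#' community of a host about which only a few phenotypes are known.
#'
#' @param dist a `latent_gmm`.
#' @param Theta K x O preferences (or a `crl_fit`).
#' @param L loadings with phenotype column names.
#' @param constraints named numeric vector of phenotype values in
#'   z-score units.
#' @param n_draws number of unbiased draws to filter (default 20000).
#' @param seed RNG seed.
#' @param tolerance half-width of the acceptance window per phenotype in
#'   SD units (default 0.2).
#' @return list with `composition` (mean, sums to 1), `n_matched`, and
#'   `matched_Z`.
#' @export
predict_from_partial_phenotypes <- function(dist, Theta, L = NULL, constraints,
                                            n_draws = 20000L, seed = 1L,
                                            tolerance = 0.2) {
  if (inherits(Theta, "crl_fit")) {
    fit <- Theta; Theta <- fit$Theta
    if (is.null(L)) L <- fit$L
  }
  if (is.null(names(constraints)) || any(!nzchar(names(constraints)))) {
    stop("constraints must be a named numeric vector", call. = FALSE)
  }
  idx <- match_target_cols(L, names(constraints))
  Z <- sample_latent(dist, n_draws, seed)
  pred <- Z %*% L[, idx, drop = FALSE]
  dev <- abs(sweep(pred, 2, constraints, "-"))
  ok <- rowSums(dev <= tolerance) == length(constraints)
  n_matched <- sum(ok)
  if (n_matched == 0) {
    stop("no generated sample satisfied all constraints; ",
         "increase n_draws or tolerance", call. = FALSE)
  }
  Q <- compose(Z[ok, , drop = FALSE], Theta)
  comp <- colMeans(Q)
  comp <- comp / sum(comp)
  list(composition = comp, n_matched = n_matched,
       matched_Z = Z[ok, , drop = FALSE])
}

#' How strongly does a single phenotype constrain the microbiome?
#'
#' Bins a generated cohort into equal-count bins of one phenotype,
#' measures the mean Bray-Curtis dissimilarity among random within-bin
#' pairs, and normalizes by the mean dissimilarity of equally many
#' unconstrained random pairs. Values near 1 mean the phenotype leaves
#' the community unconstrained; values well below 1 (especially in the
#' extreme bins) mean communities compatible with that phenotype value
#' are similar to each other.
#'
#' @param cohort a `generated_cohort` with phenotypes.
#' @param phenotype_id which phenotype to condition on.
#' @param n_bins number of quantile bins (default 10, minimum 2).
#' @param pairs_per_bin random pairs drawn per bin and for the
#'   denominator (default 1000).
#' @param seed RNG seed.
#' @return data.frame with `bin`, `center` (mean phenotype value in the
#'   bin), `n`, `normalized_bc`, `se` (standard error of the normalized
#'   value); bins with fewer than 2 samples carry `NA`.
#' @export
phenotype_constraint_profile <- function(cohort, phenotype_id, n_bins = 10L,
                                         pairs_per_bin = 1000L, seed = 1L) {
  stopifnot(inherits(cohort, "generated_cohort"))
  if (is.null(cohort$phenotypes)) stop("cohort has no phenotypes", call. = FALSE)
  if (n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  ph <- cohort$phenotypes[, phenotype_id]
  X <- cohort$compositions
  n <- length(ph)
  br <- unique(stats::quantile(ph, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(ph, breaks = br, include.lowest = TRUE, labels = FALSE)

  mean_bc_pairs <- function(rows) {
    i <- sample(rows, pairs_per_bin, replace = TRUE)
    j <- sample(rows, pairs_per_bin, replace = TRUE)
    ok <- i != j
    bc <- bray_curtis_rows(X[i[ok], , drop = FALSE], X[j[ok], , drop = FALSE])
    c(mean = mean(bc), se = stats::sd(bc) / sqrt(length(bc)))
  }
  withr_seed(seed, {
    base <- mean_bc_pairs(seq_len(n))
    rows_out <- lapply(seq_len(max(bin)), function(b) {
      rows <- which(bin == b)
      if (length(rows) < 2) {
        return(data.frame(bin = b, center = NA_real_, n = length(rows),
                          normalized_bc = NA_real_, se = NA_real_))
      }
      m <- mean_bc_pairs(rows)
      data.frame(bin = b, center = mean(ph[rows]), n = length(rows),
                 normalized_bc = unname(m["mean"] / base["mean"]),
                 se = unname(m["se"] / base["mean"]))
    })
  })
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  attr(out, "baseline_bc") <- unname(base["mean"])
  # relative SE of the normalization denominator, for error propagation
  attr(out, "baseline_se") <- unname(base["se"] / base["mean"])
  out
}

#' Local (host-specific) vs global phenotype-taxon correlations
#'
#' For each reference host, finds the `neighborhood_size` generated
#' samples closest in Bray-Curtis dissimilarity and computes, inside
#' that neighborhood, the Pearson correlation of each taxon's abundance
#' with the phenotype; the same correlation over the entire cohort gives
#' the global value. Context-dependent associations show up as local
#' correlations that differ in magnitude — or even sign — from the
#' global one; the summary regression slope of mean-local on global
#' correlations quantifies the attenuation.
#'
#' @param cohort a `generated_cohort` with phenotypes.
#' @param real_hosts an [abundance_table()] (or relative matrix) of
#'   reference hosts, same taxa as the cohort.
#' @param phenotype_id phenotype to correlate.
#' @param neighborhood_size generated neighbors per host (default 500,
#'   minimum 10).
#' @return list with `local` (hosts x taxa correlation matrix), `global`
#'   (per-taxon vector), `constant_flags` (logical matrix marking
#'   correlations set to 0 because a taxon was constant in the
#'   neighborhood), and `slope` (fit of mean-local ~ global).
#' @export
local_correlations <- function(cohort, real_hosts, phenotype_id,
                               neighborhood_size = 500L) {
  stopifnot(inherits(cohort, "generated_cohort"))
  if (is.null(cohort$phenotypes)) stop("cohort has no phenotypes", call. = FALSE)
  if (neighborhood_size < 10) {
    stop("neighborhood_size must be at least 10", call. = FALSE)
  }
  H <- composition_values(real_hosts)
  X <- cohort$compositions
  if (ncol(H) != ncol(X)) stop("taxon mismatch", call. = FALSE)
  if (neighborhood_size > nrow(X)) {
    stop("neighborhood_size exceeds cohort size", call. = FALSE)
  }
  ph <- cohort$phenotypes[, phenotype_id]

  safe_cor <- function(M, y) {
    sds <- apply(M, 2, stats::sd)
    flags <- sds == 0 | stats::sd(y) == 0
    r <- rep(0, ncol(M))
    if (!all(flags)) {
      r[!flags] <- suppressWarnings(stats::cor(M[, !flags, drop = FALSE], y))
    }
    list(r = r, flags = flags)
  }
  glob <- safe_cor(X, ph)
  nhost <- nrow(H); ntax <- ncol(X)
  local <- matrix(NA_real_, nhost, ntax)
  flags <- matrix(FALSE, nhost, ntax)
  for (h in seq_len(nhost)) {
    d <- rowSums(abs(sweep(X, 2, H[h, ]))) / 2
    nb <- order(d)[seq_len(neighborhood_size)]
    sc <- safe_cor(X[nb, , drop = FALSE], ph[nb])
    local[h, ] <- sc$r
    flags[h, ] <- sc$flags
  }
  rownames(local) <- rownames(H)
  colnames(local) <- colnames(X)
  mean_local <- colMeans(local)
  slope <- unname(stats::coef(stats::lm(mean_local ~ glob$r))[2])
  list(local = local, global = stats::setNames(glob$r, colnames(X)),
       constant_flags = flags, slope = slope)
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least `hits` members of a category of
#' size `category_size` in `draws` draws without replacement from a
#' population of `population_size`.
#'
#' @param hits observed category members among the draws.
#' @param draws number of draws.
#' @param category_size category size in the population.
#' @param population_size total population size.
#' @return the p-value `P(X >= hits)`.
#' @export
enrichment_test <- function(hits, draws, category_size, population_size) {
  if (hits < 0 || draws < 0 || category_size < 0 ||
      category_size > population_size || draws > population_size ||
      hits > min(draws, category_size)) {
    stop("inconsistent counts for hypergeometric test", call. = FALSE)
  }
  stats::phyper(hits - 1, category_size, population_size - category_size,
                draws, lower.tail = FALSE)
}
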