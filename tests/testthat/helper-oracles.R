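# Shared oracles and fixture builders. Everything is generated in code
# under fixed seeds; no stored data.

# Central finite differences of f at matrix A, step h.
num_grad <- function(A, f, h = 1e-5) {
  G <- A
  for (i in seq_along(A)) {
    Ap <- A; Am <- A
    Ap[i] <- A[i] + h
    Am[i] <- A[i] - h
    G[i] <- (f(Ap) - f(Am)) / (2 * h)
  }
  G
}

# Build a latent_gmm by hand (bypassing EM) for tests that need an
# exactly known latent distribution.
manual_gmm <- function(means, covs, weights = NULL) {
  means <- as.matrix(means)
  if (is.null(weights)) weights <- rep(1 / nrow(means), nrow(means))
  structure(list(n_components = nrow(means), weights = weights,
                 means = means, covariances = covs,
                 bic = NA_real_, loglik = NA_real_,
                 n_restarts_used = 0L, K = ncol(means)),
            class = "latent_gmm")
}

std_gmm <- function(K) manual_gmm(matrix(0, 1, K), list(diag(K)))

# Random composition vectors (rows of a Dirichlet-ish simplex draw).
random_compositions <- function(n, O, seed = 1) {
  set.seed(seed)
  g <- matrix(stats::rexp(n * O), n, O)
  g / rowSums(g)
}

# Construct a generated_cohort by hand.
manual_cohort <- function(Z, compositions, phenotypes = NULL) {
  structure(list(Z = Z, compositions = compositions, counts = NULL,
                 phenotypes = phenotypes, phenotypes_z = phenotypes,
                 seed = 0L),
            class = "generated_cohort")
}
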