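make_design_world <- function(K = 2, O = 8, P = 2, seed = 41) {
  set.seed(seed)
  Theta <- matrix(rnorm(K * O), K, O)
  L <- matrix(rnorm(K * P), K, P, dimnames = list(NULL, paste0("ph", 1:P)))
  list(gmm = std_gmm(K), Theta = Theta, L = L)
}

test_that("biased log-density reduces to the unbiased one at gamma = 0", {
  w <- make_design_world()
  Z <- matrix(rnorm(10 * 2), 10, 2)
  spec0 <- bias_spec(c(ph1 = 3), gamma = 0)
  expect_equal(biased_log_density(w$gmm, w$L, spec0, Z),
               latent_log_likelihood(w$gmm, Z))
  expect_error(biased_log_density(w$gmm, w$L, bias_spec(c(nope = 1)), Z),
               "unknown phenotype")
})

test_that("the bias term vanishes at the target and is linear in gamma", {
  w <- make_design_world()
  # a z whose predicted ph1 equals the target exactly
  target <- 1.5
  z <- target * w$L[, 1] / sum(w$L[, 1]^2)
  spec <- bias_spec(c(ph1 = target), gamma = 2)
  expect_equal(biased_log_density(w$gmm, w$L, spec, z),
               latent_log_likelihood(w$gmm, z))

  z2 <- c(0.7, -0.3)
  base <- latent_log_likelihood(w$gmm, z2)
  b1 <- biased_log_density(w$gmm, w$L, bias_spec(c(ph1 = 3), gamma = 1), z2)
  b2 <- biased_log_density(w$gmm, w$L, bias_spec(c(ph1 = 3), gamma = 2), z2)
  expect_equal(b2 - base, 2 * (b1 - base))
})

test_that("unbiased MCMC reproduces p0 moments and biasing shifts the phenotype", {
  w <- make_design_world(seed = 42)
  mc <- mcmc_config(n_chains = 40, steps = 1500, burn_in = 300, thin = 5,
                    seed = 3)
  coh0 <- sample_biased(w$gmm, w$Theta, w$L, bias_spec(c(ph1 = 3), gamma = 0),
                        mcmc = mc)
  n0 <- nrow(coh0$Z)
  se <- 1 / sqrt(n0 / 20)    # conservative SE allowing for autocorrelation
  expect_lt(max(abs(colMeans(coh0$Z))), 3 * se)

  coh2 <- sample_biased(w$gmm, w$Theta, w$L, bias_spec(c(ph1 = 3), gamma = 2),
                        mcmc = mc)
  expect_gt(mean(coh2$phenotypes_z[, "ph1"]), mean(coh0$phenotypes_z[, "ph1"]))
})

test_that("partial-phenotype prediction returns a composition and respects limits", {
  w <- make_design_world(seed = 43)
  res <- predict_from_partial_phenotypes(w$gmm, w$Theta, w$L,
                                         constraints = c(ph1 = 0.5),
                                         n_draws = 5000, seed = 2)
  expect_equal(sum(res$composition), 1, tolerance = 1e-12)
  expect_gt(res$n_matched, 0)

  # with an enormous tolerance nothing is filtered: the prediction equals
  # the unconstrained cohort mean over the same draws
  res_inf <- predict_from_partial_phenotypes(w$gmm, w$Theta, w$L,
                                             constraints = c(ph1 = 0.5),
                                             n_draws = 3000, seed = 4,
                                             tolerance = 1e6)
  expect_equal(res_inf$n_matched, 3000)
  Z <- sample_latent(w$gmm, 3000, seed = 4)
  mu <- colMeans(compose(Z, w$Theta))
  expect_equal(unname(res_inf$composition), unname(mu / sum(mu)),
               tolerance = 1e-12)

  expect_error(predict_from_partial_phenotypes(w$gmm, w$Theta, w$L,
                                               constraints = c(ph1 = 50),
                                               n_draws = 500, seed = 1),
               "increase n_draws or tolerance")
})

test_that("constraint profiles separate tied and independent phenotypes", {
  set.seed(44)
  g <- std_gmm(2)
  Theta <- matrix(rnorm(2 * 8), 2, 8)
  coh <- sample_cohort(g, Theta, n = 4000, seed = 5)
  # phenotype = abundance of taxon 1 (deterministic function of composition)
  coh$phenotypes <- cbind(tied = coh$compositions[, 1],
                          indep = rnorm(4000))
  prof_tied <- phenotype_constraint_profile(coh, "tied", n_bins = 8,
                                            pairs_per_bin = 600, seed = 6)
  expect_lt(prof_tied$normalized_bc[1], 1)
  expect_lt(prof_tied$normalized_bc[8], 1)

  prof_ind <- phenotype_constraint_profile(coh, "indep", n_bins = 8,
                                           pairs_per_bin = 600, seed = 7)
  ok <- !is.na(prof_ind$normalized_bc)
  expect_true(all(abs(prof_ind$normalized_bc[ok] - 1) <= 3 * prof_ind$se[ok] + 0.05))
})

test_that("local correlations track global ones under homogeneous coupling", {
  set.seed(45)
  g <- std_gmm(2)
  Theta <- matrix(rnorm(2 * 6), 2, 6)
  coh <- sample_cohort(g, Theta, n = 3000, seed = 8)
  # phenotype globally linear in taxon 3 with small homogeneous noise
  coh$phenotypes <- cbind(ph = coh$compositions[, 3] +
                               rnorm(3000, sd = 0.02 * sd(coh$compositions[, 3])))
  hosts <- coh$compositions[1:15, ]
  res <- local_correlations(coh, hosts, "ph", neighborhood_size = 400)
  # the driving taxon keeps its near-perfect correlation inside every
  # neighborhood; the mean-local vs global slope stays near 1
  expect_lt(abs(mean(res$local[, 3]) - res$global[3]), 0.05)
  expect_gt(res$slope, 0.6)
  expect_lt(res$slope, 1.2)
  expect_gt(cor(colMeans(res$local), res$global), 0.9)
})

test_that("planted context-dependent effects flip local correlation signs", {
  set.seed(46)
  n <- 4000
  # two latent clusters; taxon 1's association with the phenotype flips sign
  cluster <- rep(c(0, 1), each = n / 2)
  x1 <- runif(n, 0.1, 0.4)
  ph <- ifelse(cluster == 0, x1, -x1) + rnorm(n, sd = 0.02)
  rest <- matrix(runif(n * 4), n, 4)
  comp <- cbind(x1, (1 - x1) * rest / rowSums(rest))
  # separate the clusters compositionally so neighborhoods are pure
  comp[cluster == 1, 2] <- comp[cluster == 1, 2] + comp[cluster == 1, 3]
  comp[cluster == 1, 3] <- 0
  comp <- comp / rowSums(comp)
  coh <- manual_cohort(Z = matrix(cluster, ncol = 1), compositions = comp,
                       phenotypes = cbind(ph = ph))
  hosts <- comp[c(1:5, (n / 2 + 1):(n / 2 + 5)), ]
  res <- local_correlations(coh, hosts, "ph", neighborhood_size = 300)
  loc1 <- res$local[, 1]
  expect_gt(max(loc1), 0.5)
  expect_lt(min(loc1), -0.5)
  expect_lt(abs(res$global[1]), 0.35)
  # attenuating heterogeneity pulls the summary slope below 1
  expect_lt(res$slope, 1)
})

test_that("constant taxa inside a neighborhood are flagged as zero correlation", {
  set.seed(47)
  u <- runif(200, 0.2, 0.8)
  comp <- cbind(0.5, 0.5 * u, 0.5 * (1 - u))   # taxon 1 constant everywhere
  coh <- manual_cohort(Z = matrix(0, 200, 1), compositions = comp,
                       phenotypes = cbind(ph = rnorm(200)))
  res <- local_correlations(coh, comp[1:3, ], "ph", neighborhood_size = 50)
  expect_true(all(res$local[, 1] == 0))
  expect_true(all(res$constant_flags[, 1]))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(enrichment_test(0, 10, 5, 100), 1)
  # population 10, category 5, draws 5, all hits: 1 / C(10,5) = 1/252
  expect_equal(enrichment_test(5, 5, 5, 10), 1 / 252)
  # exhaustive oracle on a small case: P(X >= 2) drawing 3 from 8 with 4 marked
  draws <- combn(8, 3)
  hits2 <- mean(colSums(draws <= 4) >= 2)
  expect_equal(enrichment_test(2, 3, 4, 8), hits2)
  # tail monotonicity
  ps <- vapply(0:3, function(h) enrichment_test(h, 3, 4, 8), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(enrichment_test(6, 5, 5, 10), "inconsistent")
})
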