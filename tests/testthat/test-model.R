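test_that("compose gives uniform rows at Z = 0 and matches hand evaluation", {
  Q <- compose(matrix(0, 3, 2), matrix(rnorm(2 * 5), 2, 5))
  expect_equal(Q, matrix(1 / 5, 3, 5), ignore_attr = TRUE)

  # z = 1, theta = (0, ln 2): q = (1, 0.5) normalized = (2/3, 1/3)
  Q2 <- compose(matrix(1, 1, 1), matrix(c(0, log(2)), 1, 2))
  expect_equal(unname(Q2[1, ]), c(2 / 3, 1 / 3))

  expect_error(compose(matrix(0, 2, 3), matrix(0, 2, 4)), "dimension mismatch")
})

test_that("compose is gauge-invariant and overflow-safe with unit row sums", {
  set.seed(21)
  Z <- matrix(rnorm(6 * 3), 6, 3)
  Theta <- matrix(rnorm(3 * 8), 3, 8)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  expect_equal(compose(Z %*% A, solve(A) %*% Theta), compose(Z, Theta),
               tolerance = 1e-9)
  expect_equal(rowSums(compose(Z, Theta)), rep(1, 6), tolerance = 1e-10)
  # exponents of +-1000 would overflow a naive softmax; the shifted form
  # stays finite (entries can underflow to 0 at such extremes)
  Qbig <- compose(matrix(1000, 2, 1), matrix(c(-1, 0, 1), 1, 3))
  expect_true(all(is.finite(Qbig)) && all(Qbig >= 0))
  expect_equal(rowSums(Qbig), c(1, 1), tolerance = 1e-10)
  # at moderate exponents all entries are strictly positive
  Qmod <- compose(matrix(30, 2, 1), matrix(c(-1, 0, 1), 1, 3))
  expect_true(all(Qmod > 0))
})

test_that("microbiome_loss is the KL divergence summed over samples", {
  X <- random_compositions(4, 6, seed = 2)
  expect_equal(microbiome_loss(X, X), 0)
  expect_equal(microbiome_loss(matrix(c(1, 0), 1, 2), matrix(0.5, 1, 2)), log(2))
  Q <- random_compositions(4, 6, seed = 3)
  expect_gte(microbiome_loss(X, Q), 0)   # Gibbs inequality
  expect_error(microbiome_loss(X, Q - 0.2), "strictly positive")
})

test_that("phenotype_loss masks missing entries and matches a double-loop oracle", {
  set.seed(5)
  Z <- matrix(rnorm(8), 4, 2)
  L <- matrix(rnorm(6), 2, 3)
  raw <- Z %*% L
  # exact-prediction case: build the z-scored container directly so that
  # M$values literally equals Z L
  Mexact <- structure(list(sample_ids = paste0("s", 1:4),
                           phenotype_ids = paste0("p", 1:3),
                           values = raw, mask = matrix(TRUE, 4, 3),
                           center = rep(0, 3), scale = rep(1, 3)),
                      class = "phenotype_matrix")
  expect_equal(phenotype_loss(Mexact, Z, L), 0, tolerance = 1e-18)
  # single observed entry m = 1 predicted as 0 contributes exactly 1
  M1 <- structure(list(sample_ids = "s1", phenotype_ids = "p1",
                       values = matrix(1, 1, 1), mask = matrix(TRUE, 1, 1),
                       center = 0, scale = 1),
                  class = "phenotype_matrix")
  expect_equal(phenotype_loss(M1, matrix(0, 1, 2), matrix(0, 2, 1)), 1)

  raw2 <- raw; raw2[2, 3] <- NA; raw2[4, 1] <- NA
  M2 <- phenotype_matrix(raw2)
  oracle <- 0
  pred <- Z %*% L
  for (s in 1:4) for (p in 1:3) {
    if (M2$mask[s, p]) oracle <- oracle + (M2$values[s, p] - pred[s, p])^2
  }
  expect_equal(phenotype_loss(M2, Z, L), oracle)

  raw3 <- raw; raw3[, 2] <- NA
  expect_warning(M3 <- phenotype_matrix(raw3), "no observed values")
  expect_warning(phenotype_loss(M3, Z, L), "contribute 0")
})

test_that("combined_loss interpolates between the two objectives", {
  set.seed(6)
  X <- random_compositions(5, 7, seed = 6)
  Z <- matrix(rnorm(10), 5, 2)
  Theta <- matrix(rnorm(14), 2, 7)
  M <- phenotype_matrix(matrix(rnorm(10), 5, 2))
  L <- matrix(rnorm(4), 2, 2)
  r1 <- combined_loss(X, Z, Theta, M, L, alpha = 1)
  expect_equal(r1$C, r1$Ce)
  r0 <- combined_loss(X, Z, Theta, M, L, alpha = 0)
  expect_equal(r0$C, r0$Cm)
  ra <- combined_loss(X, Z, Theta, M, L, alpha = 0.975)
  expect_equal(ra$C, 0.975 * ra$Ce + 0.025 * ra$Cm)
  expect_error(combined_loss(X, Z, Theta, M, L, alpha = 1.2), "alpha")
  # with M absent, alpha is forced to 1
  rm <- combined_loss(X, Z, Theta, alpha = 0.3)
  expect_equal(rm$C, rm$Ce)
})

test_that("analytic gradients vanish at a perfect fit and dL is zero at alpha = 1", {
  set.seed(7)
  Z <- matrix(rnorm(8), 4, 2)
  Theta <- matrix(rnorm(10), 2, 5)
  X <- compose(Z, Theta)
  L <- matrix(rnorm(4), 2, 2)
  Mz <- Z %*% L
  M <- structure(list(sample_ids = paste0("s", 1:4),
                      phenotype_ids = c("a", "b"),
                      values = Mz, mask = matrix(TRUE, 4, 2),
                      center = c(0, 0), scale = c(1, 1)),
                 class = "phenotype_matrix")
  g <- model_gradients(X, Z, Theta, M, L, alpha = 0.5)
  expect_equal(max(abs(g$dZ)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g$dTheta)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g$dL)), 0, tolerance = 1e-12)

  g1 <- model_gradients(X, Z, Theta, M, L, alpha = 1)
  expect_equal(max(abs(g1$dL)), 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(8)
  for (rep in 1:4) {
    S <- sample(2:5, 1); O <- sample(3:6, 1); K <- sample(1:3, 1)
    P <- sample(1:3, 1); alpha <- sample(c(0, 0.5, 0.975, 1), 1)
    Z <- matrix(rnorm(S * K), S, K)
    Theta <- matrix(rnorm(K * O), K, O)
    L <- matrix(rnorm(K * P), K, P)
    X <- random_compositions(S, O, seed = 100 + rep)
    M <- phenotype_matrix(matrix(rnorm(S * P), S, P))
    if (S * P > 2) M$mask[sample(S * P, 1)] <- FALSE
    M$values[!M$mask] <- 0
    f <- function(Z, Theta, L) combined_loss(X, Z, Theta, M, L, alpha)$C
    g <- model_gradients(X, Z, Theta, M, L, alpha)
    scale <- max(abs(c(g$dZ, g$dTheta, g$dL)), 1e-8)
    expect_lt(max(abs(g$dZ - num_grad(Z, function(A) f(A, Theta, L)))) / scale, 1e-5)
    expect_lt(max(abs(g$dTheta - num_grad(Theta, function(A) f(Z, A, L)))) / scale, 1e-5)
    expect_lt(max(abs(g$dL - num_grad(L, function(A) f(Z, Theta, A)))) / scale, 1e-5)
  }
})

test_that("a full-rank factorization reproduces any composition", {
  X <- random_compositions(5, 10, seed = 9)
  cfg <- fit_config(K = 5, eta = 5e-3, grad_tol = 1e-3, max_iters = 60000,
                    seed = 1)
  fit <- fit_latent_model(abundance_table(X), cfg)
  Q <- compose(fit$Z, fit$Theta)
  kl <- vapply(1:5, function(s) kl_divergence(X[s, ], Q[s, ]), numeric(1))
  expect_lt(mean(kl), 1e-3)
})

test_that("the loss trace is non-increasing at a small constant step", {
  d <- model_based_cohort(K_true = 2, S = 15, O = 10, seed = 10)
  cfg <- fit_config(K = 2, eta = 1e-3, max_iters = 1000, seed = 2,
                    trace_every = 10)
  fit <- fit_latent_model(d$table, cfg)
  expect_false(fit$loss_increased)
  expect_true(all(diff(fit$trace$C) <= 1e-12))
})

test_that("a divergent fit aborts with advice to reduce eta", {
  d <- model_based_cohort(K_true = 2, S = 10, O = 8, seed = 11)
  cfg <- fit_config(K = 2, eta = 50, max_iters = 5000, seed = 2)
  expect_error(fit_latent_model(d$table, cfg), "smaller eta")
})

test_that("embedding training samples reproduces the training reconstruction", {
  d <- model_based_cohort(K_true = 2, S = 12, O = 10, seed = 12)
  # deep convergence so both optimizations reach the (convex-in-Z) optimum
  cfg <- fit_config(K = 2, eta = 5e-3, grad_tol = 1e-4, max_iters = 60000,
                    seed = 3)
  fit <- fit_latent_model(d$table, cfg)
  Q <- compose(fit$Z, fit$Theta)
  train_kl <- vapply(1:12, function(s) kl_divergence(d$table$values[s, ], Q[s, ]),
                     numeric(1))
  emb <- embed_samples(d$table, fit$Theta, cfg)
  expect_lt(max(abs(unname(emb$kl) - train_kl)), 1e-6)
  expect_error(embed_samples(
    abundance_table(d$table$values,
                    taxon_ids = paste0("x", 1:10)), fit$Theta, cfg),
    "taxa mismatch")
})

test_that("scramble_preferences permutes columns reproducibly", {
  set.seed(13)
  Theta <- matrix(rnorm(4 * 9), 4, 9)
  S1 <- scramble_preferences(Theta, seed = 5)
  expect_equal(sort(as.numeric(S1)), sort(as.numeric(Theta)))
  expect_equal(scramble_preferences(Theta, seed = 5), S1)
  # scrambling twice with independent seeds is again a column permutation
  S2 <- scramble_preferences(S1, seed = 6)
  cols_match <- vapply(seq_len(ncol(S2)), function(j) {
    any(vapply(seq_len(ncol(Theta)),
               function(i) isTRUE(all.equal(S2[, j], Theta[, i])), logical(1)))
  }, logical(1))
  expect_true(all(cols_match))
})

test_that("singular_spectrum exposes planted rank and matches a Gram oracle", {
  set.seed(14)
  Z <- matrix(rnorm(10 * 2), 10, 2)
  Theta <- matrix(rnorm(2 * 7), 2, 7)
  sp <- singular_spectrum(cbind(Z, 0), rbind(Theta, 0))  # K = 3, rank 2
  expect_lt(sp$values[3] / sp$values[1], 1e-10)

  sp2 <- singular_spectrum(diag(2), matrix(c(3, 0, 0, 1), 2, 2))
  expect_equal(sp2$values, c(3, 1))
  expect_equal(sp2$ratios, 3)

  # eigenvalues of the Gram matrix are squared singular values
  M <- matrix(rnorm(6 * 5), 6, 5)
  sp3 <- singular_spectrum(M, diag(5))
  ev <- sort(eigen(crossprod(M), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(sp3$values^2, ev, tolerance = 1e-8)
})

test_that("dimension_scan validates K_list and is monotone under warm starts", {
  d <- model_based_cohort(K_true = 2, S = 12, O = 8, seed = 15)
  cfg <- fit_config(K = 1, eta = 2e-3, max_iters = 8000, seed = 4)
  expect_error(dimension_scan(d$table, c(1, 20), cfg), "min\\(S, O\\)")
  expect_error(dimension_scan(d$table, c(2, 2), cfg), "distinct")
  scan <- dimension_scan(d$table, c(1, 2, 4), cfg)
  expect_equal(scan$K, c(1, 2, 4))
  expect_true(all(diff(scan$jsd) <= 1e-3))
  expect_true(all(diff(scan$bray_curtis) <= 1e-3))
})
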