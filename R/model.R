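#' Latent-variable composition model
#'
#' The core model treats a community composition as a log-linear function
#' of K sample-specific latent variables `z_sk` (time-integrated effective
#' resources, with sign absorbed) and universal species preferences
#' `theta_ko`:
#' \deqn{q_{so} = \frac{1}{\Omega_s} \exp\left(-\sum_k z_{sk}\theta_{ko}\right)}
#' with the per-sample normalizer \eqn{\Omega_s} making every row a
#' composition. An optional linear head `m_sp = sum_k z_sk L_kp` couples
#' the same latent variables to z-scored host phenotypes. Fitting
#' minimizes
#' \deqn{C = \alpha\,C_e + (1-\alpha)\,C_m}
#' where `Ce` is the Kullback-Leibler divergence between measured and
#' predicted compositions (summed over samples) and `Cm` the squared-L2
#' phenotype loss over observed entries, by constant-step gradient
#' descent.
#'
#' Only the product `Z Theta` is identifiable: any invertible K x K gauge
#' `(Z, Theta) -> (Z A, A^{-1} Theta)` leaves the compositions unchanged,
#' so downstream comparisons are made on compositions, not raw factors.
#'
#' @name composition-model
NULL

#' Compose relative abundances from latent variables and preferences
#'
#' @param Z S x K matrix of latent variables (rows = samples).
#' @param Theta K x O preference matrix (columns = taxa).
#' @return S x O matrix of strictly positive compositions; each row sums
#'   to 1. Computed with a per-row max shift so large exponents cannot
#'   overflow.
#' @export
compose <- function(Z, Theta) {
  Z <- as.matrix(Z); Theta <- as.matrix(Theta)
  if (ncol(Z) != nrow(Theta)) {
    stop("latent dimension mismatch: Z is ", nrow(Z), "x", ncol(Z),
         ", Theta is ", nrow(Theta), "x", ncol(Theta), call. = FALSE)
  }
  E <- -(Z %*% Theta)
  E <- E - row_max(E)            # overflow-safe softmax shift
  Q <- exp(E)
  Q / rowSums(Q)
}

#' Microbiome cross-entropy loss
#'
#' `Ce = sum_{s,o} x_so log(x_so / q_so)` with `0 log 0 := 0`: the KL
#' divergence of each measured composition from its model prediction,
#' summed over samples. Nonnegative, and zero exactly when `Q`
#' reproduces `X`.
#'
#' @param X observed S x O relative abundances (or an [abundance_table()]).
#' @param Q predicted compositions, strictly positive.
#' @return nonnegative total loss.
#' @export
microbiome_loss <- function(X, Q) {
  X <- composition_values(X)
  if (!all(dim(X) == dim(Q))) {
    stop("shape mismatch: X ", paste(dim(X), collapse = "x"),
         " vs Q ", paste(dim(Q), collapse = "x"), call. = FALSE)
  }
  if (any(Q <= 0)) stop("Q must be strictly positive", call. = FALSE)
  pos <- X > 0
  sum(X[pos] * log(X[pos] / Q[pos]))
}

#' Phenotype squared-L2 loss
#'
#' `Cm = sum over observed (s,p) of (m_sp - sum_k z_sk L_kp)^2`. Missing
#' entries (mask FALSE) contribute zero; a fully missing phenotype column
#' triggers a warning and contributes zero.
#'
#' @param M a [phenotype_matrix()] (z-scored, with mask).
#' @param Z S x K latent matrix.
#' @param L K x P loading matrix.
#' @return nonnegative loss.
#' @export
phenotype_loss <- function(M, Z, L) {
  stopifnot(inherits(M, "phenotype_matrix"))
  pred <- Z %*% L
  if (!all(dim(pred) == dim(M$values))) {
    stop("phenotype shape mismatch", call. = FALSE)
  }
  empty <- colSums(M$mask) == 0
  if (any(empty)) {
    warning("phenotype column(s) with no observed values contribute 0: ",
            paste(M$phenotype_ids[empty], collapse = ", "), call. = FALSE)
  }
  resid <- (M$values - pred) * M$mask
  sum(resid^2)
}

#' Combined fitting objective
#'
#' `C = alpha * Ce + (1 - alpha) * Cm`. `alpha` always weights the
#' microbiome term, so `alpha = 1` is the microbiome-only fit and
#' `alpha = 0` fits phenotypes alone.
#'
#' @inheritParams microbiome_loss
#' @inheritParams phenotype_loss
#' @param Theta K x O preference matrix.
#' @param M optional [phenotype_matrix()]; when absent `alpha` is forced
#'   to 1.
#' @param L loading matrix, required with `M`.
#' @param alpha weight in \[0, 1\] on the microbiome term.
#' @return list with `C`, `Ce`, `Cm`.
#' @export
combined_loss <- function(X, Z, Theta, M = NULL, L = NULL, alpha = 1) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (is.null(M)) alpha <- 1
  Q <- compose(Z, Theta)
  Ce <- microbiome_loss(X, Q)
  Cm <- if (is.null(M)) 0 else phenotype_loss(M, Z, L)
  list(C = alpha * Ce + (1 - alpha) * Cm, Ce = Ce, Cm = Cm)
}

#' Analytic gradients of the combined objective
#'
#' Closed-form partials of `C = alpha Ce + (1 - alpha) Cm`:
#' `dCe/dz_sk = sum_o (x_so - q_so) theta_ko`,
#' `dCe/dtheta_ko = sum_s (x_so - q_so) z_sk`,
#' `dCm/dz_sk = -2 sum_p (m_sp - pred_sp) L_kp`,
#' `dCm/dL_kp = -2 sum_s (m_sp - pred_sp) z_sk`,
#' with missing phenotype entries contributing zero.
#'
#' @inheritParams combined_loss
#' @return list with `dZ`, `dTheta`, and `dL` (zero matrix when
#'   `alpha = 1` or `M` absent).
#' @export
model_gradients <- function(X, Z, Theta, M = NULL, L = NULL, alpha = 1) {
  X <- composition_values(X)
  if (is.null(M)) alpha <- 1
  Q <- compose(Z, Theta)
  R <- X - Q
  dZ <- alpha * (R %*% t(Theta))
  dTheta <- alpha * (t(Z) %*% R)
  dL <- NULL
  if (!is.null(M)) {
    D <- (M$values - Z %*% L) * M$mask
    dZ <- dZ + (1 - alpha) * (-2 * (D %*% t(L)))
    dL <- (1 - alpha) * (-2 * (t(Z) %*% D))
  } else if (!is.null(L)) {
    dL <- matrix(0, nrow(L), ncol(L))
  }
  list(dZ = dZ, dTheta = dTheta, dL = dL)
}

composition_values <- function(X) {
  if (inherits(X, "abundance_table")) X$values else as.matrix(X)
}

#' Fit configuration
#'
#' @param K number of latent dimensions.
#' @param alpha microbiome-term weight in \[0, 1\] (1 = microbiome only;
#'   0.975 is a typical joint-fit choice that still heavily favours the
#'   composition term).
#' @param eta constant gradient-descent step size. The default 1e-3 suits
#'   cohorts of tens to hundreds of samples; drop to 1e-4 or 1e-5 if the
#'   loss does not decrease smoothly.
#' @param grad_tol stopping threshold on the sum over parameter matrices
#'   of `||grad||_2 / ||matrix||_2` (default 1e-2).
#' @param max_iters iteration cap.
#' @param seed RNG seed for the Gaussian initialization.
#' @param init_scale SD of the `Normal(0, init_scale^2)` initialization
#'   (default 0.1, keeping the initial composition near uniform).
#' @param trace_every record the loss every this many iterations.
#' @return a `fit_config` list.
#' @export
fit_config <- function(K, alpha = 1, eta = 1e-3, grad_tol = 1e-2,
                       max_iters = 20000L, seed = 1L, init_scale = 0.1,
                       trace_every = 50L) {
  if (K < 1) stop("K must be a positive integer", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (eta <= 0) stop("eta must be positive", call. = FALSE)
  if (grad_tol <= 0) stop("grad_tol must be positive", call. = FALSE)
  structure(list(K = as.integer(K), alpha = alpha, eta = eta,
                 grad_tol = grad_tol, max_iters = as.integer(max_iters),
                 seed = as.integer(seed), init_scale = init_scale,
                 trace_every = as.integer(trace_every)),
            class = "fit_config")
}

frob <- function(A) sqrt(sum(A^2))

# Fast per-row maximum (max.col is C-level; apply() is not).
row_max <- function(A) A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]

grad_ratio <- function(grads, params) {
  tot <- 0
  warned <- FALSE
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    nrm <- frob(params[[i]])
    if (nrm == 0) { warned <- TRUE; next }   # zero-norm matrix: term counted as 0
    tot <- tot + frob(grads[[i]]) / nrm
  }
  list(ratio = tot, zero_norm = warned)
}

#' Fit the latent composition model
#'
#' Initializes `Z`, `Theta` (and `L` when phenotypes are supplied) from
#' seeded `Normal(0, init_scale^2)` noise and runs constant-step gradient
#' descent on the combined objective until the summed relative gradient
#' norm drops below `grad_tol` or `max_iters` is reached. Count tables
#' are converted to relative abundances first. A transiently increasing
#' loss is recorded as a warning in the result rather than aborting —
#' constant-step descent can overshoot — but NaN/Inf loss aborts with
#' advice to lower `eta`.
#'
#' @param X an [abundance_table()] or relative-abundance matrix.
#' @param config a [fit_config()].
#' @param M optional [phenotype_matrix()] for the joint fit.
#' @return object of class `crl_fit`: `Z` (S x K), `Theta` (K x O), `L`
#'   (K x P or NULL), `scaler` (phenotype center/scale or NULL), `trace`
#'   (data.frame iter, C, Ce, Cm), `converged`, `iterations`,
#'   `loss_increased`, `config`, plus sample/taxon/phenotype ids.
#' @export
fit_latent_model <- function(X, config, M = NULL) {
  stopifnot(inherits(config, "fit_config"))
  tab <- if (inherits(X, "abundance_table")) X else abundance_table(X)
  Xv <- tab$values
  S <- nrow(Xv); O <- ncol(Xv); K <- config$K
  if (K > min(S, O)) {
    stop("K = ", K, " exceeds min(S, O) = ", min(S, O), call. = FALSE)
  }
  if (!is.null(M)) {
    stopifnot(inherits(M, "phenotype_matrix"))
    if (!identical(M$sample_ids, tab$sample_ids)) {
      if (!setequal(M$sample_ids, tab$sample_ids)) {
        stop("phenotype samples do not match abundance samples", call. = FALSE)
      }
      idx <- match(tab$sample_ids, M$sample_ids)
      M$values <- M$values[idx, , drop = FALSE]
      M$mask <- M$mask[idx, , drop = FALSE]
      M$sample_ids <- tab$sample_ids
    }
  }
  alpha <- if (is.null(M)) 1 else config$alpha
  P <- if (is.null(M)) 0L else length(M$phenotype_ids)

  withr_seed(config$seed, {
    Z <- matrix(stats::rnorm(S * K, sd = config$init_scale), S, K)
    Theta <- matrix(stats::rnorm(K * O, sd = config$init_scale), K, O)
    L <- if (P > 0) matrix(stats::rnorm(K * P, sd = config$init_scale), K, P) else NULL
  })

  res <- descend(Xv, Z, Theta, M, L, alpha, config,
                 update = c(TRUE, TRUE, P > 0))
  structure(
    list(Z = structure(res$Z, dimnames = list(tab$sample_ids, NULL)),
         Theta = structure(res$Theta, dimnames = list(NULL, tab$taxon_ids)),
         L = if (P > 0) structure(res$L, dimnames = list(NULL, M$phenotype_ids)) else NULL,
         scaler = if (P > 0) list(phenotype_ids = M$phenotype_ids,
                                  center = M$center, scale = M$scale) else NULL,
         trace = res$trace, converged = res$converged,
         iterations = res$iterations, loss_increased = res$loss_increased,
         config = config,
         sample_ids = tab$sample_ids, taxon_ids = tab$taxon_ids),
    class = "crl_fit"
  )
}

#' @export
print.crl_fit <- function(x, ...) {
  cat("crl_fit: ", nrow(x$Z), " samples, ", ncol(x$Theta), " taxa, K = ",
      ncol(x$Z), if (!is.null(x$L)) paste0(", ", ncol(x$L), " phenotypes"),
      "\n  ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "iteration cap reached",
      "; final C = ", format(utils::tail(x$trace$C, 1), digits = 6), "\n",
      sep = "")
  invisible(x)
}

# Shared constant-step descent engine. `update` flags which of
# (Z, Theta, L) move; fixed matrices are excluded from the stopping ratio.
descend <- function(Xv, Z, Theta, M, L, alpha, config, update) {
  eta <- config$eta
  trace_iter <- integer(0); trace_C <- trace_Ce <- trace_Cm <- numeric(0)
  prevC <- Inf
  loss_increased <- FALSE
  converged <- FALSE
  zero_norm_warned <- FALSE
  it <- 0L
  mask <- if (!is.null(M)) M$mask else NULL
  Mv <- if (!is.null(M)) M$values else NULL

  repeat {
    E <- -(Z %*% Theta)
    E <- E - row_max(E)
    Q <- exp(E); Q <- Q / rowSums(Q)
    R <- Xv - Q
    dZ <- alpha * (R %*% t(Theta))
    dTheta <- if (update[2]) alpha * (t(Z) %*% R) else NULL
    dL <- NULL
    if (!is.null(M) && alpha < 1) {
      D <- (Mv - Z %*% L) * mask
      dZ <- dZ + (1 - alpha) * (-2 * (D %*% t(L)))
      if (update[3]) dL <- (1 - alpha) * (-2 * (t(Z) %*% D))
    } else if (update[3] && !is.null(L)) {
      dL <- matrix(0, nrow(L), ncol(L))
    }

    pos <- Xv > 0
    Ce <- sum(Xv[pos] * log(Xv[pos] / Q[pos]))
    Cm <- if (!is.null(M)) sum(((Mv - Z %*% L) * mask)^2) else 0
    C <- alpha * Ce + (1 - alpha) * Cm
    if (!is.finite(C)) {
      stop("loss diverged (", C, ") at iteration ", it,
           "; try a smaller eta (e.g. ", format(eta / 10), ")", call. = FALSE)
    }
    if (C > prevC + 1e-12) loss_increased <- TRUE
    prevC <- C

    if (it %% config$trace_every == 0L || it == config$max_iters) {
      trace_iter <- c(trace_iter, it)
      trace_C <- c(trace_C, C); trace_Ce <- c(trace_Ce, Ce)
      trace_Cm <- c(trace_Cm, Cm)
    }

    grads <- list(dZ, if (update[2]) dTheta else NULL, if (update[3]) dL else NULL)
    params <- list(Z, Theta, L)
    gr <- grad_ratio(grads, params)
    if (gr$zero_norm && !zero_norm_warned) {
      warning("zero-norm parameter matrix in stopping ratio; its term counted as 0",
              call. = FALSE)
      zero_norm_warned <- TRUE
    }
    if (gr$ratio < config$grad_tol) { converged <- TRUE; break }
    if (it >= config$max_iters) break

    Z <- Z - eta * dZ
    if (update[2]) Theta <- Theta - eta * dTheta
    if (update[3] && !is.null(dL)) L <- L - eta * dL
    it <- it + 1L
  }

  list(Z = Z, Theta = Theta, L = L,
       trace = data.frame(iter = trace_iter, C = trace_C,
                          Ce = trace_Ce, Cm = trace_Cm),
       converged = converged, iterations = it,
       loss_increased = loss_increased)
}

#' Embed new samples under fixed preferences
#'
#' Optimizes only the latent coordinates of new samples, holding a
#' trained preference matrix fixed — the operation used to test whether
#' preferences learnt in one cohort transfer to dissimilar communities.
#' Taxa are matched (and reordered) by label.
#'
#' @param X_new an [abundance_table()] of held-out samples.
#' @param Theta trained K x O preference matrix with taxon column names,
#'   or a `crl_fit` (its `Theta` is used).
#' @param config a [fit_config()]; `K` must equal `nrow(Theta)`.
#' @return list with `Z` (S_new x K), `kl` (per-sample reconstruction
#'   KL), `Q` (fitted compositions), `converged`, `iterations`.
#' @export
embed_samples <- function(X_new, Theta, config) {
  if (inherits(Theta, "crl_fit")) Theta <- Theta$Theta
  tab <- if (inherits(X_new, "abundance_table")) X_new else abundance_table(X_new)
  if (!is.null(colnames(Theta))) {
    missing_taxa <- setdiff(colnames(Theta), tab$taxon_ids)
    extra <- setdiff(tab$taxon_ids, colnames(Theta))
    if (length(missing_taxa) || length(extra)) {
      stop("taxa mismatch; absent from new table: ",
           paste(missing_taxa, collapse = ", "),
           "; unknown to model: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    Xv <- tab$values[, colnames(Theta), drop = FALSE]
  } else {
    if (ncol(tab$values) != ncol(Theta)) {
      stop("taxa mismatch: ", ncol(tab$values), " columns vs ",
           ncol(Theta), " preferences", call. = FALSE)
    }
    Xv <- tab$values
  }
  K <- nrow(Theta)
  if (config$K != K) config$K <- K
  S <- nrow(Xv)
  withr_seed(config$seed, {
    Z <- matrix(stats::rnorm(S * K, sd = config$init_scale), S, K)
  })
  res <- descend(Xv, Z, Theta, NULL, NULL, 1, config,
                 update = c(TRUE, FALSE, FALSE))
  Q <- compose(res$Z, Theta)
  kl <- vapply(seq_len(S), function(s) kl_divergence(Xv[s, ], Q[s, ]), numeric(1))
  list(Z = structure(res$Z, dimnames = list(tab$sample_ids, NULL)),
       kl = stats::setNames(kl, tab$sample_ids), Q = Q,
       converged = res$converged, iterations = res$iterations)
}

#' Scramble a preference matrix
#'
#' Permutes the taxon columns of `Theta` with a seeded uniform
#' permutation, preserving the multiset of entries while destroying the
#' taxon-preference correspondence — the null used to show that learnt
#' preferences, not merely their distribution, carry the signal.
#'
#' @param Theta K x O preference matrix.
#' @param seed RNG seed.
#' @return permuted matrix of the same shape (original column names kept
#'   in place, so labels no longer match their preference columns).
#' @export
scramble_preferences <- function(Theta, seed = 1L) {
  perm <- withr_seed(seed, sample.int(ncol(Theta)))
  out <- Theta[, perm, drop = FALSE]
  colnames(out) <- colnames(Theta)
  out
}

#' Singular spectrum of the latent product matrix
#'
#' Singular values of `Z Theta` in descending order plus successive
#' ratios `lambda_k / lambda_{k+1}`; a sharp drop in the spectrum marks
#' the effective dimension of the latent space.
#'
#' @param Z S x K latent matrix.
#' @param Theta K x O preference matrix.
#' @return list with `values` and `ratios`.
#' @export
singular_spectrum <- function(Z, Theta) {
  if (ncol(Z) != nrow(Theta)) {
    stop("latent dimension mismatch: Z is ", nrow(Z), "x", ncol(Z),
         ", Theta is ", nrow(Theta), "x", ncol(Theta), call. = FALSE)
  }
  d <- svd(Z %*% Theta, nu = 0, nv = 0)$d
  list(values = d, ratios = d[-length(d)] / d[-1])
}

#' Scan the latent dimension
#'
#' Fits the microbiome-only model for each K in `K_list` and reports the
#' mean per-sample Jensen-Shannon distance and Bray-Curtis dissimilarity
#' between observed and fitted compositions. Both metrics flatten once K
#' exceeds the effective dimension of the data.
#'
#' Fits are run in ascending K and, by default, each is warm-started
#' from the previous solution padded with small-scale extra dimensions,
#' so a larger latent space can only improve (never worsen) the fit up
#' to optimization tolerance — the nested-capacity property a scan
#' relies on — while also cutting the scan's cost.
#'
#' @param X an [abundance_table()].
#' @param K_list distinct positive integers, each at most `min(S, O)`.
#' @param config a [fit_config()]; its `K` is overridden per scan point.
#' @param warm_start initialize each fit from the previous K's solution
#'   (default TRUE); FALSE gives independent seeded cold starts.
#' @return data.frame with columns `K`, `jsd`, `bray_curtis`, sorted by
#'   `K`.
#' @export
dimension_scan <- function(X, K_list, config, warm_start = TRUE) {
  tab <- if (inherits(X, "abundance_table")) X else abundance_table(X)
  K_list <- sort(as.integer(K_list))
  if (anyDuplicated(K_list) || any(K_list < 1)) {
    stop("K_list must be distinct positive integers", call. = FALSE)
  }
  kmax <- min(dim(tab$values))
  if (any(K_list > kmax)) {
    stop("K_list contains K > min(S, O) = ", kmax, call. = FALSE)
  }
  Xv <- tab$values
  S <- nrow(Xv)
  prev <- NULL
  out <- vector("list", length(K_list))
  for (i in seq_along(K_list)) {
    K <- K_list[i]
    cfg <- config; cfg$K <- K; cfg$alpha <- 1
    if (warm_start && !is.null(prev)) {
      extra <- K - ncol(prev$Z)
      withr_seed(cfg$seed + K, {
        Z0 <- cbind(prev$Z, matrix(stats::rnorm(S * extra, sd = cfg$init_scale),
                                   S, extra))
        Theta0 <- rbind(prev$Theta,
                        matrix(stats::rnorm(extra * ncol(Xv),
                                            sd = cfg$init_scale),
                               extra, ncol(Xv)))
      })
      res <- descend(Xv, Z0, Theta0, NULL, NULL, 1, cfg,
                     update = c(TRUE, TRUE, FALSE))
      prev <- list(Z = res$Z, Theta = res$Theta)
    } else {
      fit <- fit_latent_model(tab, cfg)
      prev <- list(Z = fit$Z, Theta = fit$Theta)
    }
    Q <- compose(prev$Z, prev$Theta)
    out[[i]] <- data.frame(K = K,
                           jsd = mean(js_distance_rows(Xv, Q)),
                           bray_curtis = mean(bray_curtis_rows(Xv, Q)))
  }
  do.call(rbind, out)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
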