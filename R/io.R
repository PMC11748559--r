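#' Reading and writing tables and fitted models
#'
#' Tables are plain delimited text (tab by default): first column the
#' sample ID, header row the taxon (or phenotype) IDs, numeric body.
#' Count tables (nonnegative whole numbers with row sums above 1) are
#' auto-detected and normalized, keeping the raw depths; phenotype
#' tables may contain blank or `NA` cells, which become missing values.
#' Fitted models are stored as a single versioned JSON archive that
#' round-trips losslessly.
#'
#' @name crlatent-io
NULL

MODEL_FORMAT_VERSION <- "crlatent-model-1"

read_delim_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("table needs a header and at least one row: ",
                              path, call. = FALSE)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  col_ids <- header[-1]
  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    stop("ragged row at line ", bad + 1, " of ", path, ": expected ",
         length(header), " fields, found ", widths[bad], call. = FALSE)
  }
  sample_ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ID '", sample_ids[duplicated(sample_ids)][1],
         "' in ", path, call. = FALSE)
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicated column ID '", col_ids[duplicated(col_ids)][1],
         "' in ", path, call. = FALSE)
  }
  body <- matrix(NA_real_, length(rows), length(col_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1]
    blank <- cells %in% c("", "NA", "na", "NaN")
    vals <- suppressWarnings(as.numeric(cells))
    bad <- !blank & is.na(vals)
    if (any(bad)) {
      stop("non-numeric cell '", cells[bad][1], "' at line ", i + 1,
           " of ", path, call. = FALSE)
    }
    body[i, ] <- vals
  }
  dimnames(body) <- list(sample_ids, col_ids)
  body
}

#' Read an abundance or phenotype table
#'
#' @param path delimited text file: first column sample IDs, header row
#'   of taxon/phenotype IDs.
#' @param kind `"abundance"` or `"phenotype"`.
#' @param sep field delimiter (default tab).
#' @param transpose set TRUE for files with taxa as rows.
#' @return an [abundance_table()] or [phenotype_matrix()].
#' @export
read_table_file <- function(path, kind = c("abundance", "phenotype"),
                            sep = "\t", transpose = FALSE) {
  kind <- match.arg(kind)
  m <- read_delim_matrix(path, sep)
  if (transpose) m <- t(m)
  if (kind == "abundance") {
    if (anyNA(m)) stop("missing values are not allowed in abundance tables",
                       call. = FALSE)
    abundance_table(m)
  } else {
    phenotype_matrix(m)
  }
}

#' Write a matrix-like table to delimited text
#'
#' Writes samples as rows with an `id` first column; the inverse of
#' [read_table_file()]. Abundance tables write their relative values
#' (or raw counts with `counts = TRUE`); phenotype matrices write
#' original units with `NA` for missing entries.
#'
#' @param x [abundance_table()], [phenotype_matrix()],
#'   `generated_cohort` (compositions), or plain matrix with dimnames.
#' @param path output file.
#' @param sep delimiter.
#' @param counts write raw counts when available.
#' @export
write_table_file <- function(x, path, sep = "\t", counts = FALSE) {
  if (inherits(x, "abundance_table")) {
    m <- if (counts && !is.null(x$counts)) x$counts else x$values
  } else if (inherits(x, "phenotype_matrix")) {
    m <- inverse_zscore(x$values, x$center, x$scale)
    m[!x$mask] <- NA
  } else if (inherits(x, "generated_cohort")) {
    m <- x$compositions
    if (is.null(rownames(m))) rownames(m) <- paste0("gen", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))
  } else {
    m <- as.matrix(x)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = sep), con)
  body <- apply(m, 1, function(r) paste(
    vapply(r, function(v) if (is.na(v)) "NA" else format(v, digits = 17),
           character(1)),
    collapse = sep))
  writeLines(paste(rownames(m), body, sep = sep), con)
  invisible(path)
}

serialize_matrix <- function(m) {
  if (is.null(m)) return(NULL)
  list(dim = dim(m), dimnames = dimnames(m), data = as.numeric(m))
}

deserialize_matrix <- function(x) {
  if (is.null(x) || length(x) == 0) return(NULL)
  m <- matrix(as.numeric(x$data), x$dim[[1]], x$dim[[2]])
  if (!is.null(x$dimnames)) {
    dn <- lapply(x$dimnames, function(d) if (length(d)) as.character(d) else NULL)
    if (any(!vapply(dn, is.null, logical(1)))) dimnames(m) <- dn
  }
  m
}

#' Save and load a fitted model archive
#'
#' The archive is a single JSON file holding the latent coordinates,
#' preferences, loadings, phenotype z-scoring parameters, fit
#' configuration, loss trace, optionally an attached latent Gaussian
#' mixture, and a format-version string. Numbers are written at full
#' precision, so `load_model(save_model(x))` reproduces `x` to better
#' than 1e-12.
#'
#' @param fit a `crl_fit`.
#' @param path archive file path.
#' @param gmm optional `latent_gmm` stored alongside.
#' @return `load_model()` returns the `crl_fit`, with the mixture (if
#'   stored) in `$gmm`.
#' @export
save_model <- function(fit, path, gmm = NULL) {
  stopifnot(inherits(fit, "crl_fit"))
  payload <- list(
    format = MODEL_FORMAT_VERSION,
    Z = serialize_matrix(fit$Z),
    Theta = serialize_matrix(fit$Theta),
    L = serialize_matrix(fit$L),
    scaler = fit$scaler,
    config = unclass(fit$config),
    trace = as.list(fit$trace),
    converged = fit$converged,
    iterations = fit$iterations,
    loss_increased = fit$loss_increased,
    sample_ids = fit$sample_ids,
    taxon_ids = fit$taxon_ids
  )
  if (!is.null(gmm)) {
    stopifnot(inherits(gmm, "latent_gmm"))
    payload$gmm <- list(
      n_components = gmm$n_components, weights = gmm$weights,
      means = serialize_matrix(gmm$means),
      covariances = lapply(gmm$covariances, serialize_matrix),
      bic = gmm$bic, loglik = gmm$loglik,
      n_restarts_used = gmm$n_restarts_used, K = gmm$K)
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) {
                    stop("cannot parse model archive ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(raw$format) || !identical(raw$format, MODEL_FORMAT_VERSION)) {
    stop("model archive version mismatch: found '", raw$format,
         "', expected '", MODEL_FORMAT_VERSION, "'", call. = FALSE)
  }
  cfg <- raw$config
  config <- fit_config(K = cfg$K, alpha = cfg$alpha, eta = cfg$eta,
                       grad_tol = cfg$grad_tol, max_iters = cfg$max_iters,
                       seed = cfg$seed, init_scale = cfg$init_scale,
                       trace_every = cfg$trace_every)
  scaler <- raw$scaler
  if (!is.null(scaler)) {
    scaler <- list(phenotype_ids = as.character(scaler$phenotype_ids),
                   center = as.numeric(scaler$center),
                   scale = as.numeric(scaler$scale))
  }
  fit <- structure(
    list(Z = deserialize_matrix(raw$Z),
         Theta = deserialize_matrix(raw$Theta),
         L = deserialize_matrix(raw$L),
         scaler = scaler,
         trace = as.data.frame(raw$trace),
         converged = raw$converged,
         iterations = raw$iterations,
         loss_increased = raw$loss_increased,
         config = config,
         sample_ids = as.character(raw$sample_ids),
         taxon_ids = as.character(raw$taxon_ids)),
    class = "crl_fit")
  if (!is.null(raw$gmm)) {
    g <- raw$gmm
    fit$gmm <- structure(
      list(n_components = g$n_components,
           weights = as.numeric(g$weights),
           means = deserialize_matrix(g$means),
           covariances = lapply(g$covariances, deserialize_matrix),
           bic = g$bic, loglik = g$loglik,
           n_restarts_used = g$n_restarts_used, K = g$K),
      class = "latent_gmm")
  }
  fit
}
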