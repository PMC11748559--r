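#' Sample-by-taxon abundance tables
#'
#' An `abundance_table` holds an S x O matrix of relative abundances
#' (samples in rows, taxa in columns, every row summing to 1), together
#' with sample and taxon labels. When built from raw counts the original
#' counts and per-sample sequencing depths are retained.
#'
#' @param values numeric S x O matrix: relative abundances or raw counts.
#' @param sample_ids,taxon_ids optional label vectors; default to
#'   dimnames or generated labels.
#' @param relative logical or NULL. `NULL` auto-detects: rows of
#'   nonnegative whole numbers whose sums exceed 1 are treated as counts
#'   and normalized.
#' @return an object of class `abundance_table` with fields `sample_ids`,
#'   `taxon_ids`, `values` (relative), `counts` (matrix or NULL), `depth`
#'   (per-sample totals or NULL).
#' @export
abundance_table <- function(values, sample_ids = NULL, taxon_ids = NULL,
                            relative = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric", call. = FALSE)
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("need at least 1 sample and 2 taxa (got ", nrow(values), " x ",
         ncol(values), ")", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite abundance entries", call. = FALSE)
  if (any(values < 0)) stop("negative abundance entries", call. = FALSE)

  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(values)
    if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(values)))
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicated taxon id: ", taxon_ids[duplicated(taxon_ids)][1], call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ", sample_ids[duplicated(sample_ids)][1], call. = FALSE)
  }

  rs <- rowSums(values)
  if (is.null(relative)) {
    whole <- all(abs(values - round(values)) < 1e-9)
    relative <- !(whole && any(rs > 1 + 1e-8))
  }
  counts <- NULL
  depth <- NULL
  if (!relative) {
    if (any(rs <= 0)) stop("count rows must have positive totals", call. = FALSE)
    counts <- values
    depth <- rs
    values <- values / rs
  } else if (any(abs(rs - 1) > 1e-8)) {
    bad <- which(abs(rs - 1) > 1e-8)[1]
    stop("relative-abundance row ", bad, " sums to ", format(rs[bad]),
         ", not 1", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(
    list(sample_ids = sample_ids, taxon_ids = taxon_ids, values = values,
         counts = counts, depth = depth),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table: ", length(x$sample_ids), " samples x ",
      length(x$taxon_ids), " taxa",
      if (!is.null(x$counts)) " (from counts)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Host phenotype matrices
#'
#' Stores an S x P matrix of host phenotype measurements, z-scored per
#' phenotype over non-missing entries (the column means and SDs are kept
#' so values can be mapped back to original units). Missing entries are
#' tracked in a logical mask and excluded from all model losses.
#'
#' @param values numeric S x P matrix in original units; `NA` = missing.
#' @param sample_ids,phenotype_ids optional labels.
#' @return object of class `phenotype_matrix` with fields `sample_ids`,
#'   `phenotype_ids`, `values` (z-scored, missing entries 0), `mask`
#'   (TRUE = observed), `center`, `scale`.
#' @export
phenotype_matrix <- function(values, sample_ids = NULL, phenotype_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("phenotype values must be numeric", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(phenotype_ids)) {
    phenotype_ids <- colnames(values)
    if (is.null(phenotype_ids)) phenotype_ids <- paste0("pheno", seq_len(ncol(values)))
  }
  if (anyDuplicated(phenotype_ids)) {
    stop("duplicated phenotype id: ",
         phenotype_ids[duplicated(phenotype_ids)][1], call. = FALSE)
  }
  mask <- !is.na(values)
  center <- numeric(ncol(values))
  scale <- numeric(ncol(values))
  z <- values
  for (p in seq_len(ncol(values))) {
    obs <- values[mask[, p], p]
    if (length(obs) == 0) {
      warning("phenotype '", phenotype_ids[p], "' has no observed values",
              call. = FALSE)
      center[p] <- 0; scale[p] <- 1
    } else {
      center[p] <- mean(obs)
      s <- stats::sd(obs)
      scale[p] <- if (length(obs) < 2 || !is.finite(s) || s == 0) 1 else s
    }
    z[, p] <- (values[, p] - center[p]) / scale[p]
  }
  z[!mask] <- 0
  dimnames(z) <- list(sample_ids, phenotype_ids)
  structure(
    list(sample_ids = sample_ids, phenotype_ids = phenotype_ids,
         values = z, mask = mask, center = center, scale = scale),
    class = "phenotype_matrix"
  )
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("phenotype_matrix: ", length(x$sample_ids), " samples x ",
      length(x$phenotype_ids), " phenotypes (",
      sum(!x$mask), " missing)\n", sep = "")
  invisible(x)
}

# Map z-scored phenotype values back to original units.
inverse_zscore <- function(z, center, scale) {
  sweep(sweep(z, 2, scale, "*"), 2, center, "+")
}

#' Aggregate rare taxa into a single "OTHER" taxon
#'
#' Taxa whose mean relative abundance across samples falls below `cutoff`
#' (default 0.1%, below which abundance variation is typically dominated
#' by technical noise) are summed into a trailing `OTHER` column. The
#' `OTHER` column is always present, even when empty, and row sums are
#' preserved.
#'
#' @param table an [abundance_table()] with relative abundances.
#' @param cutoff mean-abundance threshold (default 0.001).
#' @return a new [abundance_table()].
#' @export
aggregate_rare_taxa <- function(table, cutoff = 0.001) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$values
  keep <- colMeans(x) >= cutoff
  if (sum(keep) < 2) {
    stop("cutoff ", cutoff, " retains fewer than 2 taxa", call. = FALSE)
  }
  other <- if (all(keep)) rep(0, nrow(x)) else rowSums(x[, !keep, drop = FALSE])
  out <- cbind(x[, keep, drop = FALSE], OTHER = other)
  abundance_table(out, sample_ids = table$sample_ids,
                  taxon_ids = c(table$taxon_ids[keep], "OTHER"),
                  relative = TRUE)
}
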