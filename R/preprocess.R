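#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed as the median, over genes
#' expressed in every sample, of the ratio of the gene's count to its
#' geometric mean across samples. Dividing counts by these factors
#' normalizes library size.
#'
#' @param counts non-negative count matrix, genes x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- rbind(a = c(10, 20), b = c(30, 60), c = c(5, 10))
#' estimate_size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    stop("degenerate count matrix: no gene has positive counts in every sample",
         call. = FALSE)
  }
  lg <- log(counts[usable, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  names(sf) <- colnames(counts)
  sf
}

#' Filter genes by minimum count support
#'
#' Retains genes observed with at least `min_count` reads in at least
#' `min_samples` samples (boundaries inclusive).
#'
#' @param counts count matrix, genes x samples.
#' @param min_count,min_samples filter thresholds.
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 10, min_samples = 2) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts >= min_count) >= min_samples
  if (!any(keep)) warning("count filter removed every gene", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Filter rows by minimum across-sample variance
#'
#' Retains rows whose unbiased (n - 1 denominator) variance across samples
#' is at least `threshold`. Applied to raw per-transcript counts before
#' analysis; `threshold = 0` keeps everything.
#'
#' @param mat numeric matrix, features x samples.
#' @param threshold minimum variance retained.
#' @return the filtered matrix.
#' @export
filter_low_variance <- function(mat, threshold = 1.0) {
  mat <- as.matrix(mat)
  v <- .row_vars(mat)
  mat[v >= threshold, , drop = FALSE]
}

.row_vars <- function(mat) {
  n <- ncol(mat)
  if (n < 2) return(rep(NA_real_, nrow(mat)))
  rowSums((mat - rowMeans(mat))^2) / (n - 1)
}

#' Shifted-log variance-damping transform
#'
#' `log2(count / size_factor + pseudocount)`: a monotone, exactly
#' reproducible variance-damping transform of size-factor-normalized
#' counts, used here where heavier regularized-log transforms would rely
#' on model-internal shrinkage. A zero count maps to `log2(pseudocount)`
#' (0 at the default), and the value is invariant to jointly scaling a
#' sample's counts and size factor.
#'
#' @param counts count matrix, genes x samples.
#' @param size_factors from [estimate_size_factors()].
#' @param pseudocount positive shift added after normalization.
#' @return log2-scale matrix with a `provenance` attribute `"shifted-log"`.
#' @export
shifted_log_transform <- function(counts, size_factors, pseudocount = 1) {
  if (pseudocount <= 0) stop("`pseudocount` must be positive", call. = FALSE)
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(size_factors))
  out <- log2(sweep(counts, 2, size_factors, `/`) + pseudocount)
  attr(out, "provenance") <- "shifted-log"
  out
}

#' Estimate a single surrogate variable by residual PCA
#'
#' Fits, per gene, ordinary least squares on the protected factors plus
#' the known batch factor, and returns the first principal component
#' across samples of the residual matrix as a single surrogate variable
#' (SV) capturing structured variation not explained by the design. The
#' SV is centred to zero mean and scaled to unit norm; its sign is fixed
#' by making its largest-magnitude element positive. If the residuals are
#' numerically zero the SV is undefined and a zero vector is returned with
#' a warning.
#'
#' @param expr expression matrix (log2 scale), genes x samples.
#' @param meta sample table with the `protected` and `batch` columns.
#' @param protected column names of factors whose effects must be
#'   preserved (default diet and tissue).
#' @param batch column name of the known batch factor.
#' @return list of class `design_info`: `sv` (named numeric), `batch`
#'   (factor), `protected` (data frame), `sv_defined` (logical).
#' @export
estimate_surrogate_variable <- function(expr, meta,
                                        protected = c("diet", "tissue"),
                                        batch = "batch") {
  expr <- as.matrix(expr)
  stopifnot(all(c(protected, batch) %in% names(meta)),
            ncol(expr) == nrow(meta))
  dat <- as.data.frame(lapply(meta[c(protected, batch)], factor))
  X <- model.matrix(~ ., dat)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
  if (nrow(X) < ncol(X) + 2) {
    stop("need at least 2 more samples than design columns", call. = FALSE)
  }
  hat <- X %*% solve(crossprod(X), t(X))
  resid <- expr - expr %*% hat
  sv <- rep(0, ncol(expr))
  defined <- max(abs(resid)) > 1e-10 * max(1, max(abs(expr)))
  if (!defined) {
    warning("residual matrix is numerically zero; surrogate variable undefined",
            call. = FALSE)
  } else {
    v <- svd(resid, nu = 0, nv = 1)$v[, 1]
    v <- v - mean(v)
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    sv <- v
  }
  names(sv) <- colnames(expr)
  structure(
    list(sv = sv, batch = factor(meta[[batch]]),
         protected = as.data.frame(lapply(meta[protected], factor)),
         sv_defined = defined),
    class = "design_info"
  )
}

#' Remove batch and surrogate-variable effects from expression
#'
#' Per gene, fits least squares on the protected factors, the batch
#' factor and the surrogate variable jointly, and subtracts only the
#' fitted batch and SV components, leaving protected-factor group means
#' unchanged up to numerical tolerance. Errors if batch is confounded
#' with a protected factor.
#'
#' @param expr expression matrix (log2 scale), genes x samples.
#' @param design_info from [estimate_surrogate_variable()].
#' @return corrected matrix with `provenance` attribute
#'   `"batch-corrected"`; gene and sample index sets are untouched.
#' @export
remove_batch_effects <- function(expr, design_info) {
  stopifnot(inherits(design_info, "design_info"))
  expr <- as.matrix(expr)
  Xp <- model.matrix(~ ., design_info$protected)
  Xb <- model.matrix(~ design_info$batch)[, -1, drop = FALSE]
  if (qr(cbind(Xp, Xb))$rank < ncol(Xp) + ncol(Xb)) {
    stop("batch factor is confounded with a protected factor", call. = FALSE)
  }
  cov <- NULL
  if (design_info$sv_defined) cov <- design_info$sv
  out <- limma::removeBatchEffect(expr, batch = design_info$batch,
                                  covariates = cov, design = Xp)
  dimnames(out) <- dimnames(expr)
  attr(out, "provenance") <- "batch-corrected"
  out
}
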