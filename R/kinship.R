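#' Marker-inferred kinship matrix
#'
#' Computes the raw marker-inferred relationship matrix
#' `K' = (1/m) * sum_k Z_k Z_k^T` over all `m` loci, where `Z_k` is the column
#' of genotype codes for locus k. No allele-frequency centering or scaling is
#' applied — the trace rescale (see [rescale_kinship()]) is the model's sole
#' normalisation, making the polygenic variance comparable with the residual
#' variance. Monomorphic loci are retained by default (they contribute a
#' constant block); set `drop_monomorphic = TRUE` to exclude zero-variance
#' loci from the sum. Missing genotypes are imputed with the per-locus mean
#' before the cross product (a message reports the count).
#'
#' @param geno Genotype matrix, individuals in rows, loci in columns, codes in
#'   \{-1, 0, 1\} (NA allowed).
#' @param drop_monomorphic Drop zero-variance loci before computing K'.
#' @param check_psd Verify positive semi-definiteness (eigenvalues >=
#'   `-1e-8 * max eigenvalue`); tiny negative eigenvalues are tolerated, larger
#'   ones raise an error.
#' @return An `n x n` symmetric matrix with a logical attribute `rescaled`
#'   (FALSE here) and row/column names from `rownames(geno)`.
#' @seealso [rescale_kinship()], [kinship()]
#' @export
compute_kinship <- function(geno, drop_monomorphic = FALSE, check_psd = TRUE) {
  if (is.null(dim(geno)) || ncol(geno) < 1) abort("Genotype matrix has no loci.")
  if (nrow(geno) < 2) abort("Kinship needs at least 2 individuals.")
  Z <- geno
  storage.mode(Z) <- "double"
  if (anyNA(Z)) {
    n_missing <- sum(is.na(Z))
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2]]
    rlang::inform(sprintf("Imputed %d missing genotype(s) with per-locus means.", n_missing))
  }
  if (drop_monomorphic) {
    v <- apply(Z, 2, var)
    keep <- v > 0
    if (!any(keep)) abort("All loci are monomorphic.")
    Z <- Z[, keep, drop = FALSE]
  }
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  if (check_psd) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      abort("Kinship matrix is not positive semi-definite.")
    }
  }
  rownames(K) <- colnames(K) <- rownames(geno)
  attr(K, "rescaled") <- FALSE
  K
}

#' Rescale a kinship matrix to trace n
#'
#' Applies the trace normalisation `K = n * K' / tr(K')`, which puts the
#' polygenic variance on the same per-observation scale as the residual
#' variance (so that heritability is the simple ratio of the two components).
#'
#' @param K_prime Kinship matrix from [compute_kinship()] (or any symmetric
#'   PSD matrix).
#' @return The rescaled matrix, with `attr(, "rescaled") = TRUE` and
#'   `trace = nrow(K)`.
#' @export
rescale_kinship <- function(K_prime) {
  tr <- sum(diag(K_prime))
  if (tr <= 0) abort("Kinship trace must be positive (all-monomorphic panel?).")
  n <- nrow(K_prime)
  K <- n * K_prime / tr
  attr(K, "rescaled") <- TRUE
  K
}

#' Rescaled kinship in one step
#'
#' Convenience wrapper: `rescale_kinship(compute_kinship(geno, ...))`. This is
#' the matrix that enters all model fitting.
#'
#' @inheritParams compute_kinship
#' @param ... Passed to [compute_kinship()].
#' @return Rescaled kinship matrix (trace = n).
#' @export
kinship <- function(geno, ...) {
  rescale_kinship(compute_kinship(geno, ...))
}
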