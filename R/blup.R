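#' Solve the genomic-selection Henderson equations
#'
#' Given variance components, computes the BLUE of the fixed effects and the
#' BLUP of the polygenic values. Two algebraically equivalent routes are
#' available:
#'
#' * `"henderson"` (default): solves the block system
#'   `[X'X, X'; X, I + K^-1 / lambda] [beta; xi] = [X'y; y]`
#'   with `lambda = sigma_A^2 / sigma^2`. If `K` is numerically singular a
#'   tiny ridge (`1e-8 * tr(K)/n` on the diagonal) is applied before
#'   inversion and a warning issued.
#' * `"vinverse"`: `beta = (X'V^-1 X)^-1 X'V^-1 y` and
#'   `xi = sigma_A^2 K V^-1 (y - X beta)` with `V = K sigma_A^2 + I sigma^2`;
#'   this route never inverts `K` itself and is stable as `lambda -> 0`
#'   (where `xi -> 0` and `beta` tends to ordinary least squares).
#'
#' @inheritParams reml_fit
#' @param varcomp A `gblup_varcomp` object (or a list with `sigma_A2`,
#'   `sigma2`).
#' @param route `"henderson"` or `"vinverse"`.
#' @return An object of class `gblup_blup`: list with `beta` (BLUE), `xi`
#'   (BLUP, named by individual when `K` has dimnames), `fitted`
#'   (`X beta + xi`), `varcomp`, `route`.
#' @export
henderson_solve <- function(y, K, varcomp, X = NULL,
                            route = c("henderson", "vinverse")) {
  route <- match.arg(route)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(K) != n || nrow(X) != n) abort("Dimensions of `y`, `X`, `K` do not agree.")
  sA2 <- varcomp$sigma_A2
  s2 <- varcomp$sigma2
  if (s2 <= 0) abort("`sigma2` must be positive.")
  lambda <- sA2 / s2

  if (route == "henderson") {
    Kinv <- tryCatch(solve(K), error = function(e) NULL)
    if (is.null(Kinv) || !all(is.finite(Kinv))) {
      warn("`K` is numerically singular; adding a 1e-8 * tr(K)/n ridge.")
      Kinv <- solve(K + diag(1e-8 * sum(diag(K)) / n, n))
    }
    C <- rbind(
      cbind(crossprod(X), t(X)),
      cbind(X, diag(n) + Kinv / lambda)
    )
    kap <- kappa(C, exact = FALSE)
    if (kap > 1e10) {
      warn(sprintf("Henderson system is ill-conditioned (kappa ~ %.2g).", kap))
    }
    sol <- solve(C, c(crossprod(X, y), y))
    beta <- sol[seq_len(ncol(X))]
    xi <- sol[-seq_len(ncol(X))]
  } else {
    V <- sA2 * K + diag(s2, n)
    Vi_y <- solve(V, y)
    Vi_X <- solve(V, X)
    beta <- as.numeric(solve(crossprod(X, Vi_X), crossprod(X, Vi_y)))
    resid <- y - X %*% beta
    xi <- as.numeric(sA2 * (K %*% solve(V, resid)))
  }
  names(xi) <- rownames(K)
  structure(
    list(beta = as.numeric(beta), xi = xi,
         fitted = as.numeric(X %*% beta + xi),
         varcomp = varcomp, route = route),
    class = "gblup_blup"
  )
}

#' Predict genetic values of held-out individuals
#'
#' Conditional-expectation (BLUP) prediction for individuals whose phenotypes
#' did not enter the fit:
#' `yhat_2 = X_2 beta + K_21 sigma_A^2 (K_11 sigma_A^2 + I sigma^2)^-1 (y_1 - X_1 beta)`
#' with `K_11` (train x train) and `K_21` (test x train) sliced from the full
#' kinship, and predicted genetic values `xi_2 = yhat_2 - X_2 beta` (fixed
#' effects removed). Information flows only through `K_21`, the genomic
#' covariance between test and training individuals: a test individual
#' genomically unrelated to the panel is predicted at the fixed effects alone.
#'
#' @param y Full phenotype vector; only the training entries are used.
#' @param K Full kinship matrix covering training and test individuals.
#' @param varcomp Variance components (typically estimated on the training
#'   set).
#' @param test Integer indices of the test individuals.
#' @param X Fixed-effect design for all individuals (default intercept).
#' @param beta Optional fixed-effect estimate; when `NULL`, the GLS estimate
#'   is computed on the training set under `varcomp`.
#' @return Object of class `gblup_prediction`: list with `test` (indices),
#'   `xi2_hat`, `y2_hat`, `beta`.
#' @export
predict_holdout <- function(y, K, varcomp, test, X = NULL, beta = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  test <- as.integer(test)
  if (length(test) == 0) abort("Test set is empty.")
  if (any(test < 1 | test > n)) abort("Test indices out of range.")
  if (anyDuplicated(test)) abort("Test indices contain duplicates.")
  train <- setdiff(seq_len(n), test)
  if (length(train) == 0) abort("Training set is empty.")
  sA2 <- varcomp$sigma_A2
  s2 <- varcomp$sigma2

  y1 <- y[train]
  X1 <- X[train, , drop = FALSE]
  X2 <- X[test, , drop = FALSE]
  V11 <- sA2 * K[train, train, drop = FALSE] + diag(s2, length(train))
  if (is.null(beta)) {
    Vi_X1 <- solve(V11, X1)
    beta <- as.numeric(solve(crossprod(X1, Vi_X1), crossprod(Vi_X1, y1)))
  }
  resid1 <- y1 - X1 %*% beta
  xi2 <- as.numeric(sA2 * K[test, train, drop = FALSE] %*% solve(V11, resid1))
  y2 <- as.numeric(X2 %*% beta) + xi2
  structure(
    list(test = test, xi2_hat = xi2, y2_hat = y2, beta = as.numeric(beta)),
    class = "gblup_prediction"
  )
}

#' Fit the GBLUP model to a phenotype table
#'
#' One-stop fit: aligns a phenotype tibble with a genotype or kinship matrix,
#' estimates variance components by [reml_fit()], and solves the Henderson
#' equations for the BLUE/BLUP. Phenotypes with replicates should be averaged
#' first (see [average_replicates()]).
#'
#' @param pheno Tibble with columns `id` and `value`, one row per individual.
#' @param geno Genotype matrix with row names matching `pheno$id`; the
#'   rescaled kinship is computed internally. Ignored when `K` is given.
#' @param K Precomputed (rescaled) kinship matrix with dimnames matching
#'   `pheno$id`.
#' @param X Optional fixed-effect design matrix (default intercept-only).
#' @param method `"REML"` or `"ML"`.
#' @return Object of class `gblup_fit`: list with `varcomp`, `blup`
#'   (`gblup_blup`), `h2`, `data` (list of `y`, `X`, `K`, `ids`).
#' @examples
#' m <- genetic_map(60, 3, 100)
#' Z <- simulate_ril_genotypes(m, 80, seed = 1)
#' sim <- simulate_phenotypes(Z, 0.2, 1, replicates = 4, seed = 2)
#' fit <- sim$phenotypes |> average_replicates() |> gblup(geno = Z)
#' glance(fit)
#' @export
gblup <- function(pheno, geno = NULL, K = NULL, X = NULL,
                  method = c("REML", "ML")) {
  method <- match.arg(method)
  check_pheno(pheno)
  if (anyDuplicated(pheno$id)) {
    abort("One phenotype per individual expected; average replicates first.")
  }
  if (is.null(K)) {
    if (is.null(geno)) abort("Supply either `geno` or `K`.")
    K <- kinship(geno)
  }
  ids <- pheno$id
  if (!is.null(rownames(K))) {
    if (!all(ids %in% rownames(K))) abort("Some phenotype ids are missing from the kinship matrix.")
    K <- K[ids, ids]
  } else if (nrow(K) != nrow(pheno)) {
    abort("Unnamed kinship must match the phenotype table in size.")
  }
  y <- pheno$value
  vc <- reml_fit(y, K, X = X, method = method)
  bl <- henderson_solve(y, K, vc, X = X)
  structure(
    list(varcomp = vc, blup = bl, h2 = heritability(vc),
         data = list(y = y, X = X, K = K, ids = ids)),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> n = %d individuals\n", x$varcomp$n))
  print(x$varcomp)
  invisible(x)
}

#' @rdname gblup
#' @param x,object A `gblup_fit` object.
#' @param ... Unused.
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble::tibble(
    id = x$data$ids,
    value = x$data$y,
    xi_hat = as.numeric(x$blup$xi),
    fitted = x$blup$fitted
  )
}

#' @rdname gblup
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  vc <- x$varcomp
  tibble::tibble(
    sigma_A2 = vc$sigma_A2, sigma2 = vc$sigma2, lambda = vc$lambda,
    h2 = x$h2, loglik = vc$loglik, method = vc$method,
    converged = vc$converged, n = vc$n
  )
}

#' @rdname gblup
#' @method tidy gblup_varcomp
#' @export
tidy.gblup_varcomp <- function(x, ...) {
  tibble::tibble(
    component = c("sigma_A2", "sigma2"),
    estimate = c(x$sigma_A2, x$sigma2)
  )
}

#' @rdname gblup
#' @method glance gblup_varcomp
#' @export
glance.gblup_varcomp <- function(x, ...) {
  tibble::tibble(
    sigma_A2 = x$sigma_A2, sigma2 = x$sigma2, lambda = x$lambda,
    h2 = heritability(x), loglik = x$loglik, method = x$method,
    converged = x$converged, n = x$n
  )
}
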