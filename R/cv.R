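#' Build k-fold cross-validation plans
#'
#' Each repeat draws a uniformly random permutation of the individuals and
#' cuts it into `k` contiguous blocks whose sizes differ by at most one, so
#' every individual is tested exactly once per repeat.
#'
#' @param n Number of individuals.
#' @param k Number of folds (`2 <= k <= n`).
#' @param repeats Number of independent repartitions.
#' @param seed Optional integer seed (local RNG scope); identical seeds give
#'   identical plans.
#' @return A tibble with columns `repeat_index`, `index` (individual position
#'   1..n) and `fold`.
#' @examples
#' make_folds(10, 5, seed = 1)
#' @export
make_folds <- function(n, k, repeats = 1, seed = NULL) {
  if (k < 2) abort("`k` must be at least 2.")
  if (k > n) abort("`k` cannot exceed `n`.")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  run <- function() {
    purrr::map_dfr(seq_len(repeats), function(rep_i) {
      perm <- sample.int(n)
      tibble::tibble(
        repeat_index = rep_i,
        index = perm,
        fold = rep(seq_len(k), times = sizes)
      )
    })
  }
  with_seed_if(seed, run()) |> dplyr::arrange(.data$repeat_index, .data$index)
}

#' Cross-validated heritability from predicted genetic values
#'
#' The genetic variance is taken to be the sample variance of the genetic
#' values predicted through cross validation, and the residual variance the
#' sample variance of the differences between the (fixed-effect-centered)
#' observed phenotypes and those predictions:
#' `Hcv = Var(xi_cv) / (Var(xi_cv) + Var(y_centered - xi_cv))`.
#' Because each prediction is made while the individual sits in the test
#' fold, trait-irrelevant markers cannot inflate the genetic variance the way
#' they do in a whole-data fit.
#'
#' @param xi_cv Cross-validation-predicted genetic values, one per individual.
#' @param y_centered Observed phenotypes with each individual's fold-specific
#'   fixed effects (`X_2 beta_hat`) removed.
#' @return Heritability estimate in `[0, 1]`.
#' @seealso [cv_heritability_alt()], [predictability()], [cv_gblup()]
#' @export
cv_heritability <- function(xi_cv, y_centered) {
  if (length(xi_cv) != length(y_centered)) abort("Vector lengths differ.")
  vg <- var(xi_cv)
  vr <- var(y_centered - xi_cv)
  if (vg + vr == 0) abort("Zero total variance.")
  vg / (vg + vr)
}

#' Alternative cross-validated heritability
#'
#' The ratio of the variance of the cross-validation-predicted genetic values
#' to the observed phenotypic variance, `Var(xi_cv) / Var(y)`.
#'
#' @inheritParams cv_heritability
#' @param y Observed phenotypes (uncentered).
#' @return Ratio estimate (>= 0).
#' @export
cv_heritability_alt <- function(xi_cv, y) {
  if (length(xi_cv) != length(y)) abort("Vector lengths differ.")
  vy <- var(y)
  if (vy == 0) abort("Zero phenotypic variance.")
  var(xi_cv) / vy
}

#' Predictability: squared correlation of observed and predicted values
#'
#' `Pcv = cor(y_centered, xi_cv)^2`, pooled over all individuals of a repeat.
#' Constant predictions return 0 with a warning rather than an error.
#'
#' @inheritParams cv_heritability
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
predictability <- function(xi_cv, y_centered) {
  if (length(xi_cv) != length(y_centered)) abort("Vector lengths differ.")
  if (sd(xi_cv) == 0) {
    warn("Predicted genetic values are constant; predictability set to 0.")
    return(0)
  }
  if (sd(y_centered) == 0) abort("Observed phenotypes are constant.")
  cor(y_centered, xi_cv)^2
}

#' Whole-data (non-cross-validated) heritability
#'
#' The conventional benchmark: variance components are estimated by REML on
#' the full data and plugged into `h2 = sigma_A^2 / (sigma_A^2 + sigma^2)`.
#' With many trait-irrelevant markers in the kinship this estimate overfits
#' upward, which is what the cross-validated estimators are designed to
#' control.
#'
#' @inheritParams reml_fit
#' @return Heritability in `[0, 1]`.
#' @export
naive_heritability <- function(y, K, X = NULL, method = "REML") {
  heritability(reml_fit(y, K, X = X, method = method))
}

#' k-fold cross-validated GBLUP: Hcv, Hcv_alt and Pcv
#'
#' Runs the full cross-validation pipeline on a phenotype table. For each
#' fold, variance components and fixed effects are (by default) re-estimated
#' on the k-1 training folds only, and the genetic values of the test fold
#' are predicted by conditional expectation ([predict_holdout()]); after all
#' folds, every individual carries exactly one prediction obtained without
#' its own phenotype contributing to training. Kinship is computed once from
#' all genotypes and sliced per fold (genotypes carry no phenotype
#' information, so this is not leakage).
#'
#' @inheritParams gblup
#' @param k Number of folds (default 5).
#' @param repeats Number of independent repartitions (default 1).
#' @param seed Optional integer seed for the fold plans.
#' @param folds Optional precomputed plan from [make_folds()] (overrides `k`,
#'   `repeats`, `seed`).
#' @param varcomp_mode `"per_fold"` (default; leak-free) re-estimates variance
#'   components within every training fold. `"global"` estimates them once on
#'   the full data — predictions are still cross-validated, but the components
#'   have seen every phenotype, so this mode is partially leaky and provided
#'   for comparison only.
#' @return Object of class `gblup_cv`: list with
#'   * `results` — tibble of `repeat_index`, `Hcv`, `Hcv_alt`, `Pcv`;
#'   * `predictions` — tibble of `repeat_index`, `id`, `fold`, `xi_hat_cv`,
#'     `y_centered`;
#'   * `beta_by_fold` — tibble of per-fold fixed-effect estimates;
#'   * `summary` — mean and standard deviation of each measure across repeats;
#'   * `k`, `varcomp_mode`.
#' @examples
#' m <- genetic_map(100, 4, 100)
#' Z <- simulate_ril_genotypes(m, 60, seed = 1)
#' sim <- simulate_phenotypes(Z, 0.2, 1, seed = 2)
#' cv <- cv_gblup(sim$phenotypes, geno = Z, k = 5, seed = 3)
#' glance(cv)
#' @export
cv_gblup <- function(pheno, geno = NULL, K = NULL, X = NULL, k = 5,
                     repeats = 1, seed = NULL, folds = NULL,
                     varcomp_mode = c("per_fold", "global"),
                     method = c("REML", "ML")) {
  varcomp_mode <- match.arg(varcomp_mode)
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
  if (!is.null(rownames(K))) K <- K[ids, ids]
  y <- pheno$value
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (is.null(folds)) folds <- make_folds(n, k, repeats = repeats, seed = seed)
  k <- max(folds$fold)

  global_vc <- if (varcomp_mode == "global") reml_fit(y, K, X = X, method = method)

  per_repeat <- lapply(split(folds, folds$repeat_index), function(plan) {
    xi_cv <- numeric(n)
    y_cent <- numeric(n)
    fold_of <- integer(n)
    betas <- vector("list", k)
    for (f in seq_len(k)) {
      test <- plan$index[plan$fold == f]
      train <- setdiff(seq_len(n), test)
      if (length(train) < ncol(X) + 1) {
        abort("A training fold is smaller than the fixed-effect rank + 1.")
      }
      vc <- if (varcomp_mode == "per_fold") {
        reml_fit(y[train], K[train, train, drop = FALSE],
                 X = X[train, , drop = FALSE], method = method)
      } else global_vc
      pred <- predict_holdout(y, K, vc, test = test, X = X)
      xi_cv[test] <- pred$xi2_hat
      y_cent[test] <- y[test] - as.numeric(X[test, , drop = FALSE] %*% pred$beta)
      fold_of[test] <- f
      betas[[f]] <- pred$beta
    }
    list(
      pred = tibble::tibble(
        repeat_index = plan$repeat_index[1], id = ids, fold = fold_of,
        xi_hat_cv = xi_cv, y_centered = y_cent
      ),
      beta = tibble::tibble(
        repeat_index = plan$repeat_index[1], fold = seq_len(k),
        beta = purrr::map(betas, identity)
      ),
      res = tibble::tibble(
        repeat_index = plan$repeat_index[1],
        Hcv = cv_heritability(xi_cv, y_cent),
        Hcv_alt = cv_heritability_alt(xi_cv, y),
        Pcv = predictability(xi_cv, y_cent)
      )
    )
  })

  results <- purrr::map_dfr(per_repeat, "res")
  summary <- results |>
    tidyr::pivot_longer(-"repeat_index", names_to = "measure") |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")

  structure(
    list(
      results = results,
      predictions = purrr::map_dfr(per_repeat, "pred"),
      beta_by_fold = purrr::map_dfr(per_repeat, "beta"),
      summary = summary,
      k = k, varcomp_mode = varcomp_mode
    ),
    class = "gblup_cv"
  )
}

#' @export
print.gblup_cv <- function(x, ...) {
  cat(sprintf("<gblup_cv> %d-fold, %d repeat(s), varcomp mode '%s'\n",
              x$k, nrow(x$results), x$varcomp_mode))
  print(x$summary)
  invisible(x)
}

#' @rdname cv_gblup
#' @param x A `gblup_cv` object.
#' @param ... Unused.
#' @method tidy gblup_cv
#' @export
tidy.gblup_cv <- function(x, ...) x$results

#' @rdname cv_gblup
#' @method glance gblup_cv
#' @export
glance.gblup_cv <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "measure", values_from = c("mean", "sd"),
                       names_glue = "{measure}_{.value}") |>
    dplyr::mutate(k = x$k, repeats = nrow(x$results),
                  varcomp_mode = x$varcomp_mode)
}
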