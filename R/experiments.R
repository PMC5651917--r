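#' Simulation experiment: signal levels, per-replicate vs averaged analysis
#'
#' Simulates a RIL panel once, then for each per-locus effect standard
#' deviation in `sigma_g_grid` (residual sd fixed at `sigma_e`) generates
#' `replicates` technical replicates per line and analyses the data three
#' ways: GBLUP on each replicate separately (effective sample size n), GBLUP
#' on the replicate average (effective sample size n * r), and the
#' line-plus-replicate ANOVA on all n * r observations. For every GBLUP
#' analysis the whole-data heritability `H`, the cross-validated heritability
#' `Hcv` and the predictability `Pcv` are reported.
#'
#' @param n Number of lines (default 210).
#' @param map Genetic map (default: [genetic_map()] with 1619 loci on 12
#'   chromosomes).
#' @param sigma_g_grid Per-locus effect standard deviations to sweep
#'   (default `c(1/50, 1/20, 1/10)`).
#' @param sigma_e Residual standard deviation (default 1).
#' @param replicates Technical replicates per line (default 4).
#' @param k,cv_repeats Cross-validation settings.
#' @param seed Integer seed; the whole experiment is reproducible under it.
#' @return A tibble with columns `sigma_g`, `analysis` (`"rep_1"`, ...,
#'   `"average"`, `"anova"`), `sample_size`, `H`, `Hcv`, `Pcv`, `Haov`
#'   (`Haov` only on the anova rows), plus attribute `seed`.
#' @export
experiment_signal_grid <- function(n = 210, map = genetic_map(),
                                   sigma_g_grid = c(1 / 50, 1 / 20, 1 / 10),
                                   sigma_e = 1, replicates = 4, k = 5,
                                   cv_repeats = 1, seed = NULL) {
  run <- function() {
    Z <- simulate_ril_genotypes(map, n)
    K <- kinship(Z)
    out <- purrr::map_dfr(sigma_g_grid, function(sg) {
      sim <- simulate_phenotypes(Z, sg, sigma_e, replicates = replicates)
      ph <- sim$phenotypes
      gs_rows <- purrr::map_dfr(seq_len(replicates), function(r) {
        pr <- ph |> dplyr::filter(.data$replicate == r)
        cv <- cv_gblup(pr, K = K, k = k, repeats = cv_repeats)
        tibble::tibble(
          analysis = paste0("rep_", r), sample_size = n,
          H = naive_heritability(pr$value, K),
          Hcv = mean(cv$results$Hcv), Pcv = mean(cv$results$Pcv),
          Haov = NA_real_
        )
      })
      pa <- average_replicates(ph)
      cva <- cv_gblup(pa, K = K, k = k, repeats = cv_repeats)
      avg_row <- tibble::tibble(
        analysis = "average", sample_size = n * replicates,
        H = naive_heritability(pa$value, K),
        Hcv = mean(cva$results$Hcv), Pcv = mean(cva$results$Pcv),
        Haov = NA_real_
      )
      aov_row <- tibble::tibble(
        analysis = "anova", sample_size = n * replicates,
        H = NA_real_, Hcv = NA_real_, Pcv = NA_real_,
        Haov = anova_heritability(ph)$Haov
      )
      dplyr::bind_rows(gs_rows, avg_row, aov_row) |>
        dplyr::mutate(sigma_g = sg, .before = 1)
    })
    attr(out, "seed") <- seed
    out
  }
  with_seed_if(seed, run())
}

#' Simulation experiment: replicate count vs estimator behaviour
#'
#' On one fixed simulated panel (fixed genotypes and locus effects), varies
#' the number of technical replicates per line. For each replicate count `r`,
#' fresh errors are drawn, the ANOVA heritability is computed from all n * r
#' observations, and the GBLUP estimators (`H`, `Hcv`, `Pcv`) are computed on
#' the replicate-averaged phenotypes. Averaging shrinks the residual variance
#' like 1/r, so the cross-validated estimators climb with r while the ANOVA
#' heritability stays put.
#'
#' @inheritParams experiment_signal_grid
#' @param rep_grid Replicate counts to sweep (default `c(10, 50, 100, 500)`).
#' @param sigma_g Per-locus effect sd (default 1/20).
#' @param anova Compute the ANOVA column. With `anova = TRUE` a grid entry of
#'   `r = 1` propagates the documented ANOVA error (replicates required); set
#'   `anova = FALSE` to sweep GBLUP-only grids that include `r = 1`.
#' @return A tibble with columns `n_replicates`, `Haov`, `H`, `Hcv`, `Pcv`.
#' @export
experiment_replicate_grid <- function(n = 210, map = genetic_map(),
                                      rep_grid = c(10, 50, 100, 500),
                                      sigma_g = 1 / 20, sigma_e = 1,
                                      k = 5, cv_repeats = 1, anova = TRUE,
                                      seed = NULL) {
  run <- function() {
    Z <- simulate_ril_genotypes(map, n)
    K <- kinship(Z)
    gamma <- rnorm(ncol(Z), 0, sigma_g)
    xi <- as.numeric(Z %*% gamma)
    ids <- rownames(Z)
    out <- purrr::map_dfr(rep_grid, function(r) {
      err <- matrix(rnorm(n * r, 0, sigma_e), n, r)
      ph <- tibble::tibble(
        id = rep(ids, times = r),
        replicate = rep(seq_len(r), each = n),
        value = rep(xi, times = r) + as.numeric(err)
      )
      haov <- if (anova) anova_heritability(ph)$Haov else NA_real_
      pa <- average_replicates(ph)
      cv <- cv_gblup(pa, K = K, k = k, repeats = cv_repeats)
      tibble::tibble(
        n_replicates = r, Haov = haov,
        H = naive_heritability(pa$value, K),
        Hcv = mean(cv$results$Hcv), Pcv = mean(cv$results$Pcv)
      )
    })
    attr(out, "seed") <- seed
    out
  }
  with_seed_if(seed, run())
}
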