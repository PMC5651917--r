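#' ANOVA heritability for replicated lines
#'
#' The comparison baseline for replicated designs: all `n x r` observations
#' are fit with the two-factor fixed-effects model
#' `value ~ factor(id) + factor(replicate)`, and the between-line variance is
#' recovered from the balanced-design mean squares on a single-observation
#' basis: `var_line = (MS_line - MS_error) / r` and
#' `Haov = var_line / (var_line + MS_error)`. A negative `var_line` is
#' truncated to 0 with a warning. Unlike the genomic estimators, this measure
#' does not improve with additional replicates — the between-line contrast is
#' already saturated — which is exactly the deficiency the cross-validated
#' genomic estimators expose.
#'
#' @param pheno Phenotype tibble with columns `id`, `replicate`, `value`;
#'   the design must be balanced with at least 2 lines and 2 replicates per
#'   line (with a single replicate the between/within decomposition is
#'   undefined — use the genomic-selection path instead).
#' @return A one-row tibble: `ms_line`, `ms_replicate`, `ms_error`,
#'   `var_line`, `var_error`, `Haov`, `n_lines`, `n_replicates`.
#' @examples
#' m <- genetic_map(50, 2, 100)
#' Z <- simulate_ril_genotypes(m, 40, seed = 1)
#' sim <- simulate_phenotypes(Z, 0.2, 1, replicates = 4, seed = 2)
#' anova_heritability(sim$phenotypes)
#' @export
anova_heritability <- function(pheno) {
  check_pheno(pheno)
  if (!"replicate" %in% names(pheno)) {
    abort("ANOVA needs a `replicate` column.")
  }
  counts <- table(pheno$id)
  r <- unique(as.integer(counts))
  if (length(r) != 1) abort("Unbalanced design: lines differ in replicate count.")
  if (r < 2) {
    abort(paste(
      "ANOVA heritability requires replicated measurements (>= 2 per line);",
      "for single measurements use the genomic-selection estimators instead."
    ))
  }
  if (length(counts) < 2) abort("ANOVA needs at least 2 lines.")
  fit <- aov(value ~ factor(id) + factor(replicate), data = pheno)
  tab <- anova(fit)
  ms <- setNames(tab[["Mean Sq"]], rownames(tab))
  ms_line <- ms[["factor(id)"]]
  ms_rep <- ms[["factor(replicate)"]]
  ms_err <- ms[["Residuals"]]
  var_line <- (ms_line - ms_err) / r
  if (var_line < 0) {
    warn("Negative between-line variance estimate truncated to 0.")
    var_line <- 0
  }
  haov <- if (var_line + ms_err == 0) 0 else var_line / (var_line + ms_err)
  tibble::tibble(
    ms_line = ms_line, ms_replicate = ms_rep, ms_error = ms_err,
    var_line = var_line, var_error = ms_err,
    Haov = min(max(haov, 0), 1),
    n_lines = length(counts), n_replicates = r
  )
}
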