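#' Incremental-locus scan of H, Hcv and Pcv
#'
#' Reproduces the overfitting demonstration: loci are sorted by the strength
#' of their marginal association with the phenotype (absolute Pearson
#' correlation, strongest first), and the model is refit on nested top-`p`
#' fractions of the sorted list. For each fraction the whole-data heritability
#' `H`, the cross-validated heritability `Hcv` and the predictability `Pcv`
#' are recorded. As trait-irrelevant loci are appended, `H` keeps climbing
#' (overfitting) while `Hcv` and `Pcv` stabilise once the causal loci are
#' covered.
#'
#' @inheritParams cv_gblup
#' @param geno Genotype matrix (required; the kinship is recomputed for every
#'   locus subset).
#' @param step Fraction of loci added at each step (default 0.1).
#' @param k,repeats,seed Cross-validation settings (see [cv_gblup()]).
#' @return A tibble of class `gblup_scan` with columns `prop_loci`, `n_loci`,
#'   `H`, `Hcv`, `Pcv` (Hcv/Pcv averaged over repeats), plus attribute
#'   `locus_order` (the sorted locus indices).
#' @examples
#' m <- genetic_map(100, 4, 100)
#' Z <- simulate_ril_genotypes(m, 60, seed = 1)
#' sim <- simulate_phenotypes(Z, 0.3, 1, seed = 2, causal = 1:20)
#' scan_loci(sim$phenotypes, Z, step = 0.25, seed = 3)
#' @export
scan_loci <- function(pheno, geno, step = 0.1, k = 5, repeats = 1,
                      seed = NULL) {
  check_pheno(pheno)
  if (anyDuplicated(pheno$id)) {
    abort("One phenotype per individual expected; average replicates first.")
  }
  if (step <= 0 || step > 1) abort("`step` must be in (0, 1].")
  geno <- geno[pheno$id, , drop = FALSE]
  y <- pheno$value
  m <- ncol(geno)
  assoc <- abs(suppressWarnings(cor(geno, y)))[, 1]
  assoc[is.na(assoc)] <- 0 # monomorphic loci: no association
  ord <- order(assoc, decreasing = TRUE)
  fracs <- unique(c(seq(step, 1, by = step), 1))
  rows <- purrr::map_dfr(fracs, function(p) {
    top <- ord[seq_len(max(1, round(p * m)))]
    Ksub <- kinship(geno[, top, drop = FALSE])
    cv <- cv_gblup(pheno, K = Ksub, k = k, repeats = repeats, seed = seed)
    tibble::tibble(
      prop_loci = p,
      n_loci = length(top),
      H = naive_heritability(y, Ksub),
      Hcv = mean(cv$results$Hcv),
      Pcv = mean(cv$results$Pcv)
    )
  })
  attr(rows, "locus_order") <- ord
  class(rows) <- c("gblup_scan", class(rows))
  rows
}
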