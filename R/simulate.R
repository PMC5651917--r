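#' Simulate recombinant inbred line (RIL) genotypes
#'
#' Generates fully homozygous lines (marker codes in \{-1, 1\}; 1 = A1A1,
#' -1 = A2A2) from a biparental cross at fixation. Lines are generated
#' chromosome by chromosome as a Markov chain over loci ordered by map
#' position: the first locus of each chromosome is -1 or 1 with probability
#' 1/2, and each subsequent locus disagrees with its left neighbour with the
#' RIL-by-selfing discordance probability R = 2r/(1+2r), where r is the
#' Haldane recombination fraction for the intervening map distance. Loci on
#' different chromosomes segregate independently.
#'
#' Two-locus discordance for *adjacent* loci matches the selfing expectation
#' exactly; for non-adjacent loci the chained construction is a close
#' approximation (discordance is very slightly inflated relative to a
#' generation-explicit selfing pedigree).
#'
#' @param map Genetic map tibble from [genetic_map()] (columns `chrom`,
#'   `locus`, `pos_cm`).
#' @param n Number of lines to simulate (>= 2).
#' @param seed Optional integer seed. When supplied, the simulation is run in
#'   a locally seeded RNG scope so the caller's RNG state is untouched;
#'   identical seeds reproduce identical output.
#'
#' @return An integer matrix of dimension `n` x `nrow(map)` with row names
#'   `line_0001`, ... and column names taken from `map$locus`. Entries are
#'   -1 or 1 (RILs carry no heterozygotes).
#' @examples
#' m <- genetic_map(n_loci = 30, n_chr = 3, chr_length = 100)
#' Z <- simulate_ril_genotypes(m, n = 50, seed = 1)
#' table(Z)
#' @export
simulate_ril_genotypes <- function(map, n, seed = NULL) {
  validate_map(map)
  if (length(n) != 1 || is.na(n) || n < 2) abort("`n` must be a single integer >= 2.")
  n <- as.integer(n)
  run <- function() {
    m <- nrow(map)
    Z <- matrix(NA_integer_, n, m)
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      Z[, idx[1]] <- sample(c(-1L, 1L), n, replace = TRUE)
      if (length(idx) > 1) {
        d <- diff(map$pos_cm[idx])
        R <- ril_discordance(haldane_r(d))
        for (j in seq_along(d)) {
          flip <- stats::rbinom(n, 1L, R[j])
          Z[, idx[j + 1]] <- Z[, idx[j]] * (1L - 2L * flip)
        }
      }
    }
    dimnames(Z) <- list(sprintf("line_%04d", seq_len(n)), map$locus)
    Z
  }
  with_seed_if(seed, run())
}

#' Simulate polygenic phenotypes with technical replicates
#'
#' Draws one additive effect per locus, `gamma_k ~ N(0, sigma_g^2)`, forms the
#' polygenic value of each line as `xi_j = sum_k Z[j,k] * gamma_k`, and emits
#' `replicates` measurements per line, each `xi_j + e` with independent
#' `e ~ N(0, sigma_e^2)` (simple technical replicates: the genetic value is
#' identical across replicates and there is no block effect). Draw order is
#' fixed for reproducibility: all locus effects first, then errors
#' replicate-major (all lines of replicate 1, then replicate 2, ...).
#'
#' @param geno Genotype matrix (lines x loci, codes in \{-1, 0, 1\}), e.g.
#'   from [simulate_ril_genotypes()].
#' @param sigma_g Standard deviation of a per-locus effect (> 0).
#' @param sigma_e Residual standard deviation (> 0).
#' @param replicates Number of technical replicates per line (>= 1).
#' @param seed Optional integer seed (local RNG scope).
#' @param causal Optional integer vector of locus column indices carrying
#'   nonzero effects; loci outside `causal` are neutral (effect exactly 0).
#'   Defaults to all loci. `integer(0)` yields a pure-noise trait
#'   (`Var(xi) = 0`).
#'
#' @return A list of class `sim_phenotypes`:
#'   * `phenotypes` — tibble with columns `id`, `replicate`, `value`;
#'   * `genetic_values` — tibble with columns `id`, `xi` (the true polygenic
#'     values, retained for recovery checks);
#'   * `effects` — list with `gamma` (length-m effect vector), `sigma_g`,
#'     `sigma_e`.
#' @examples
#' m <- genetic_map(20, 2, 100)
#' Z <- simulate_ril_genotypes(m, 40, seed = 1)
#' sim <- simulate_phenotypes(Z, sigma_g = 0.2, sigma_e = 1, replicates = 4, seed = 2)
#' head(sim$phenotypes)
#' @export
simulate_phenotypes <- function(geno, sigma_g, sigma_e, replicates = 1,
                                seed = NULL, causal = NULL) {
  if (is.null(dim(geno)) || ncol(geno) < 1) abort("`geno` must have at least one locus.")
  if (sigma_g <= 0) abort("`sigma_g` must be positive.")
  if (sigma_e <= 0) abort("`sigma_e` must be positive.")
  if (replicates < 1) abort("`replicates` must be at least 1.")
  n <- nrow(geno)
  m <- ncol(geno)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("line_%04d", seq_len(n))
  if (is.null(causal)) causal <- seq_len(m)
  if (length(causal) > 0 && (any(causal < 1) || any(causal > m))) {
    abort("`causal` indices out of range.")
  }
  run <- function() {
    gamma <- numeric(m)
    if (length(causal) > 0) gamma[causal] <- rnorm(length(causal), 0, sigma_g)
    xi <- as.numeric(geno %*% gamma)
    err <- matrix(rnorm(n * replicates, 0, sigma_e), nrow = n, ncol = replicates)
    pheno <- tibble::tibble(
      id = rep(ids, times = replicates),
      replicate = rep(seq_len(replicates), each = n),
      value = rep(xi, times = replicates) + as.numeric(err)
    )
    structure(
      list(
        phenotypes = pheno,
        genetic_values = tibble::tibble(id = ids, xi = xi),
        effects = list(gamma = gamma, sigma_g = sigma_g, sigma_e = sigma_e)
      ),
      class = "sim_phenotypes"
    )
  }
  with_seed_if(seed, run())
}

#' Average technical replicates
#'
#' Collapses a phenotype table to one record per individual, taking the
#' arithmetic mean across that individual's replicates. When given a
#' `sim_phenotypes` object the true genetic values are carried through
#' unchanged.
#'
#' @param pheno A phenotype tibble with columns `id`, `replicate`, `value`, or
#'   a `sim_phenotypes` object.
#' @return Same shape as the input: a tibble with one row per individual
#'   (`replicate` set to 1), or a `sim_phenotypes` object whose `phenotypes`
#'   element is averaged.
#' @examples
#' ph <- tibble::tibble(id = "a", replicate = 1:4, value = 1:4)
#' average_replicates(ph)
#' @export
average_replicates <- function(pheno) {
  if (inherits(pheno, "sim_phenotypes")) {
    pheno$phenotypes <- average_replicates(pheno$phenotypes)
    return(pheno)
  }
  check_pheno(pheno)
  pheno |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(replicate = 1L, .after = "id")
}

check_pheno <- function(pheno) {
  if (!all(c("id", "value") %in% names(pheno))) {
    abort("Phenotype table needs columns `id` and `value`.")
  }
  if (nrow(pheno) == 0) abort("Phenotype table is empty.")
  if (anyNA(pheno$value)) abort("Phenotype values contain NA.")
  if ("replicate" %in% names(pheno) &&
      anyDuplicated(pheno[, c("id", "replicate")])) {
    abort("Each (id, replicate) pair may appear at most once.")
  }
  invisible(pheno)
}

# Evaluate `expr` under a local, seeded RNG when seed is given; otherwise use
# the current RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
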