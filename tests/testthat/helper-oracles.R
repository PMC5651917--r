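# Independent oracles used across the suite. These deliberately avoid the
# computational shortcuts of the package implementation (eigendecomposition /
# profile likelihood / matrix cross products) so that agreement is evidence,
# not tautology.

# Dense evaluation of the restricted (or full) log likelihood
#   L = -1/2 ln|V| - 1/2 ln|X'V^-1 X| - 1/2 (y - Xb)' V^-1 (y - Xb),
# V = K*sA2 + I*s2, b the GLS estimate, via explicit Cholesky factors.
dense_loglik <- function(y, X, K, sA2, s2, reml = TRUE) {
  n <- length(y)
  V <- K * sA2 + diag(s2, n)
  R <- chol(V)
  ldV <- 2 * sum(log(diag(R)))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  A <- crossprod(X, Vi_X)
  b <- solve(A, crossprod(X, Vi_y))
  r <- y - X %*% b
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  ll <- -0.5 * ldV - 0.5 * sum(r * Vi_r)
  if (reml) ll <- ll - 0.5 * determinant(A, logarithm = TRUE)$modulus
  as.numeric(ll)
}

# Brute-force grid search of the likelihood surface over (sA2, s2).
grid_reml_oracle <- function(y, X, K, grid_n = 200, reml = TRUE) {
  hi <- 10 * var(y)
  sA2_grid <- seq(1e-4, hi, length.out = grid_n)
  s2_grid <- seq(1e-4, hi, length.out = grid_n)
  best <- -Inf
  arg <- c(NA, NA)
  for (s2 in s2_grid) {
    for (sA2 in sA2_grid) {
      ll <- dense_loglik(y, X, K, sA2, s2, reml = reml)
      if (ll > best) {
        best <- ll
        arg <- c(sA2, s2)
      }
    }
  }
  list(loglik = best, sigma_A2 = arg[1], sigma2 = arg[2],
       cell = c(diff(sA2_grid[1:2]), diff(s2_grid[1:2])))
}

# Generation-explicit selfing simulator for a single chromosome: F1
# heterozygotes selfed for `generations` rounds, recombination per meiosis at
# the single-meiosis fractions `r` between adjacent loci (Haldane, no
# interference). Returns the n x L matrix of (essentially fixed) genotypes.
meiosis_ril_oracle <- function(r, n, generations = 30) {
  L <- length(r) + 1
  hapA <- matrix(1, n, L)
  hapB <- matrix(-1, n, L)
  gamete <- function(hapA, hapB) {
    ch <- matrix(FALSE, n, L)
    ch[, 1] <- stats::runif(n) < 0.5
    for (l in seq_along(r)) {
      sw <- stats::runif(n) < r[l]
      ch[, l + 1] <- xor(ch[, l], sw)
    }
    hapA * ch + hapB * (1 - ch)
  }
  for (g in seq_len(generations)) {
    g1 <- gamete(hapA, hapB)
    g2 <- gamete(hapA, hapB)
    hapA <- g1
    hapB <- g2
  }
  hapA
}

# Per-locus outer-product kinship, written as the literal loop-based sum.
loop_kinship_oracle <- function(Z) {
  n <- nrow(Z)
  m <- ncol(Z)
  K <- matrix(0, n, n)
  for (k in seq_len(m)) {
    K <- K + Z[, k] %o% Z[, k]
  }
  K / m
}

# Two-pass sample variance (sum of squares about a first-pass mean).
two_pass_var <- function(x) {
  mu <- sum(x) / length(x)
  sum((x - mu)^2) / (length(x) - 1)
}

# Small random GBLUP instance with a full-rank kinship.
random_instance <- function(n, m = 3 * n, q = 1, h2 = 0.5) {
  Z <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
  K <- cvherit::kinship(Z)
  X <- if (q == 1) matrix(1, n, 1) else cbind(1, matrix(rnorm(n * (q - 1)), n))
  U <- eigen(K, symmetric = TRUE)
  xi <- as.numeric(U$vectors %*% (sqrt(pmax(U$values, 0)) * rnorm(n))) * sqrt(h2)
  y <- as.numeric(X %*% rnorm(q)) + xi + rnorm(n, sd = sqrt(1 - h2))
  list(y = y, X = X, K = K, Z = Z)
}
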