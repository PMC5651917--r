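test_that("RIL genotypes are fully homozygous, balanced and seed-deterministic", {
  map <- genetic_map(n_loci = 25, n_chr = 5, chr_length = 120)
  Z1 <- simulate_ril_genotypes(map, n = 500, seed = 42)
  Z2 <- simulate_ril_genotypes(map, n = 500, seed = 42)
  expect_identical(Z1, Z2)
  expect_true(all(Z1 %in% c(-1L, 1L)))
  expect_identical(dim(Z1), c(500L, 25L))
  expect_identical(colnames(Z1), map$locus)

  # per-locus mean code shrinks like 1/sqrt(n)
  Zbig <- simulate_ril_genotypes(genetic_map(5, 5, 100), n = 20000, seed = 42)
  expect_true(all(abs(colMeans(Zbig)) < 3 / sqrt(20000)))
})

test_that("zero map distance gives perfect concordance, other chromosomes independence", {
  map0 <- tibble::tibble(chrom = c(1L, 1L), locus = c("a", "b"), pos_cm = c(5, 5))
  Z <- simulate_ril_genotypes(map0, n = 2000, seed = 42)
  expect_identical(Z[, 1], Z[, 2])

  map2 <- tibble::tibble(chrom = c(1L, 2L), locus = c("a", "b"), pos_cm = c(0, 0))
  Z2 <- simulate_ril_genotypes(map2, n = 10000, seed = 42)
  expect_lt(abs(cor(Z2[, 1], Z2[, 2])), 0.05)
})

test_that("adjacent-locus discordance follows 2r/(1+2r) and decays with distance", {
  n <- 20000
  for (d in c(10, 50)) {
    map <- tibble::tibble(chrom = 1L, locus = c("a", "b"), pos_cm = c(0, d))
    Z <- simulate_ril_genotypes(map, n = n, seed = 42 + d)
    r <- (1 - exp(-2 * d / 100)) / 2
    R <- 2 * r / (1 + 2 * r)
    obs <- mean(Z[, 1] != Z[, 2])
    se <- sqrt(R * (1 - R) / n)
    expect_lt(abs(obs - R), 2 * se)
  }
  # LD (genotype correlation) is decreasing in map distance
  cors <- vapply(c(5, 20, 80), function(d) {
    map <- tibble::tibble(chrom = 1L, locus = c("a", "b"), pos_cm = c(0, d))
    Z <- simulate_ril_genotypes(map, n = 20000, seed = 7)
    cor(Z[, 1], Z[, 2])
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("Markov fixation sim matches a generation-explicit selfing oracle on adjacent pairs", {
  n <- 20000
  d <- c(10, 10)
  r <- (1 - exp(-2 * d / 100)) / 2
  map <- tibble::tibble(chrom = 1L, locus = c("a", "b", "c"), pos_cm = c(0, 10, 20))
  Z <- simulate_ril_genotypes(map, n = n, seed = 42)
  set.seed(43)
  Zo <- meiosis_ril_oracle(r, n = n, generations = 30)
  expect_true(all(Zo %in% c(-1, 1)))
  for (pair in list(c(1, 2), c(2, 3))) {
    obs <- mean(Z[, pair[1]] != Z[, pair[2]])
    orc <- mean(Zo[, pair[1]] != Zo[, pair[2]])
    theo <- 2 * r[1] / (1 + 2 * r[1])
    se <- sqrt(theo * (1 - theo) / n)
    expect_lt(abs(obs - orc), 2 * sqrt(2) * se)
    expect_lt(abs(orc - theo), 3 * se)
  }
})

test_that("phenotype simulation has the stated structure and draw determinism", {
  map <- genetic_map(40, 4, 100)
  Z <- simulate_ril_genotypes(map, n = 500, seed = 1)
  s1 <- simulate_phenotypes(Z, sigma_g = 0.1, sigma_e = 1, replicates = 4, seed = 9)
  s2 <- simulate_phenotypes(Z, sigma_g = 0.1, sigma_e = 1, replicates = 4, seed = 9)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$effects$gamma, s2$effects$gamma)

  # xi identical across replicates: value - xi are pure errors
  wide <- tidyr::pivot_wider(s1$phenotypes, names_from = "replicate",
                             values_from = "value")
  errs <- as.matrix(wide[, -1]) - s1$genetic_values$xi
  # residual variance of the replicate mean is sigma_e^2 / 4
  # (sample variance over n lines has relative sd sqrt(2/(n-1)); allow 3 sd)
  v <- var(rowMeans(errs))
  expect_lt(abs(v - 1 / 4), 3 * sqrt(2 / 499) * (1 / 4))
  # each replicate column has unit error variance
  expect_lt(abs(mean(apply(errs, 2, var)) - 1), 0.15)
})

test_that("causal subsets and the zero-effect override behave", {
  map <- genetic_map(30, 3, 100)
  Z <- simulate_ril_genotypes(map, n = 50, seed = 1)
  s <- simulate_phenotypes(Z, 0.5, 1, seed = 2, causal = 1:5)
  expect_true(all(s$effects$gamma[6:30] == 0))
  expect_true(any(s$effects$gamma[1:5] != 0))
  s0 <- simulate_phenotypes(Z, 0.5, 1, seed = 2, causal = integer(0))
  expect_identical(s0$genetic_values$xi, rep(0, 50))
  expect_identical(var(s0$genetic_values$xi), 0)
})

test_that("average_replicates takes arithmetic means and passes truth through", {
  ph <- tibble::tibble(id = rep(c("a", "b"), each = 4),
                       replicate = rep(1:4, 2),
                       value = c(1, 2, 3, 4, 10, 10, 10, 10))
  out <- average_replicates(ph)
  expect_equal(out$value[out$id == "a"], 2.5)
  expect_equal(out$value[out$id == "b"], 10)

  single <- tibble::tibble(id = "x", replicate = 1L, value = 3.3)
  expect_equal(average_replicates(single)$value, 3.3)

  map <- genetic_map(10, 1, 50)
  Z <- simulate_ril_genotypes(map, n = 10, seed = 1)
  sim <- simulate_phenotypes(Z, 0.2, 1, replicates = 4, seed = 2)
  avg <- average_replicates(sim)
  expect_identical(avg$genetic_values, sim$genetic_values)
  expect_equal(nrow(avg$phenotypes), 10)
})

test_that("simulator input validation", {
  map <- genetic_map(10, 2, 50)
  expect_error(simulate_ril_genotypes(map, n = 1), ">= 2")
  expect_error(simulate_ril_genotypes(map[0, ], n = 10), "empty")
  Z <- simulate_ril_genotypes(map, 10, seed = 1)
  expect_error(simulate_phenotypes(Z[, 0, drop = FALSE], 0.1, 1), "locus")
  expect_error(simulate_phenotypes(Z, -1, 1), "sigma_g")
  expect_error(simulate_phenotypes(Z, 0.1, 0), "sigma_e")
})
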