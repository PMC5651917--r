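test_that("fold plans are balanced, exhaustive and seed-deterministic", {
  f <- make_folds(10, 5, seed = 42)
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))
  expect_setequal(f$index, 1:10)

  f210 <- make_folds(210, 10, seed = 42)
  expect_equal(as.integer(table(f210$fold)), rep(21L, 10))

  expect_identical(make_folds(50, 5, repeats = 3, seed = 1),
                   make_folds(50, 5, repeats = 3, seed = 1))
  expect_false(identical(make_folds(50, 5, seed = 1), make_folds(50, 5, seed = 2)))

  f7 <- make_folds(7, 3, seed = 1)
  expect_lte(diff(range(table(f7$fold))), 1)

  expect_error(make_folds(5, 6), "exceed")
  expect_error(make_folds(5, 1), "at least 2")
})

test_that("an individual's phenotype never reaches the training side of its test fold", {
  set.seed(42)
  map <- genetic_map(80, 4, 100)
  Z <- simulate_ril_genotypes(map, 40, seed = 1)
  sim <- simulate_phenotypes(Z, 0.2, 1, seed = 2)
  ph <- sim$phenotypes
  K <- kinship(Z)
  folds <- make_folds(40, 5, seed = 3)
  cv1 <- cv_gblup(ph, K = K, folds = folds)
  # perturb one phenotype: its own CV prediction must be unchanged, because
  # it is only ever predicted from folds that exclude it
  i <- 17
  ph2 <- ph
  ph2$value[i] <- ph2$value[i] + 50
  cv2 <- cv_gblup(ph2, K = K, folds = folds)
  expect_identical(cv1$predictions$xi_hat_cv[i], cv2$predictions$xi_hat_cv[i])
  # and every individual is predicted exactly once per repeat
  expect_equal(sort(cv1$predictions$id), sort(ph$id))
})

test_that("cross-validated heritability identities and the variance oracle hold", {
  set.seed(1)
  y <- rnorm(50)
  yc <- y - mean(y)
  expect_equal(cv_heritability(yc, yc), 1)     # perfect prediction
  expect_equal(cv_heritability(rep(0, 50), yc), 0)
  expect_equal(cv_heritability_alt(rep(0, 50), y), 0)
  expect_equal(cv_heritability_alt(y, y), 1)
  expect_warning(p0 <- predictability(rep(0, 50), yc), "constant")
  expect_equal(p0, 0)
  expect_equal(predictability(2 * yc + 3, yc), 1) # affine invariance

  xi <- rnorm(50)
  vg <- two_pass_var(xi)
  vr <- two_pass_var(yc - xi)
  expect_equal(cv_heritability(xi, yc), vg / (vg + vr), tolerance = 1e-12)
  expect_equal(cv_heritability_alt(xi, y), vg / two_pass_var(y), tolerance = 1e-12)
})

test_that("a near-noiseless trait puts Pcv near its ceiling with Hcv alongside", {
  map <- genetic_map(200, 4, 100)
  Z <- simulate_ril_genotypes(map, 100, seed = 42)
  sim <- simulate_phenotypes(Z, sigma_g = 1, sigma_e = 0.05, seed = 43)
  cv <- cv_gblup(sim$phenotypes, geno = Z, k = 5, seed = 44)
  expect_gt(cv$results$Pcv, 0.9)
  expect_lt(abs(cv$results$Hcv - cv$results$Pcv), 0.05)
})

test_that("a pure-noise trait yields Hcv and Pcv near zero", {
  map <- genetic_map(300, 6, 100)
  Z <- simulate_ril_genotypes(map, 210, seed = 42)
  sim <- simulate_phenotypes(Z, sigma_g = 1, sigma_e = 1, seed = 43,
                             causal = integer(0))
  cv <- cv_gblup(sim$phenotypes, geno = Z, k = 5, repeats = 10, seed = 44)
  expect_lt(mean(cv$results$Hcv), 0.05)
  expect_lt(mean(cv$results$Pcv), 0.05)
})

test_that("global variance-component mode runs and is labelled", {
  map <- genetic_map(60, 3, 100)
  Z <- simulate_ril_genotypes(map, 40, seed = 1)
  sim <- simulate_phenotypes(Z, 0.2, 1, seed = 2)
  cv <- cv_gblup(sim$phenotypes, geno = Z, k = 4, seed = 3,
                 varcomp_mode = "global")
  expect_identical(cv$varcomp_mode, "global")
  expect_true(all(cv$results$Hcv >= 0 & cv$results$Hcv <= 1))
})

test_that("tidiers return the documented shapes", {
  map <- genetic_map(60, 3, 100)
  Z <- simulate_ril_genotypes(map, 40, seed = 1)
  sim <- simulate_phenotypes(Z, 0.2, 1, seed = 2)
  cv <- cv_gblup(sim$phenotypes, geno = Z, k = 4, repeats = 2, seed = 3)
  expect_named(tidy(cv), c("repeat_index", "Hcv", "Hcv_alt", "Pcv"))
  expect_equal(nrow(tidy(cv)), 2)
  g <- glance(cv)
  expect_true(all(c("Hcv_mean", "Hcv_sd", "Pcv_mean", "Pcv_sd") %in% names(g)))

  fit <- gblup(sim$phenotypes, geno = Z)
  expect_named(tidy(fit), c("id", "value", "xi_hat", "fitted"))
  expect_equal(nrow(tidy(fit)), 40)
  expect_true(all(c("sigma_A2", "sigma2", "h2", "loglik") %in% names(glance(fit))))
})
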