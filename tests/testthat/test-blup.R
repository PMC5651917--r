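test_that("Henderson and V-inverse routes agree on random instances", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    inst <- random_instance(n = n, h2 = runif(1, 0.2, 0.8))
    vc <- reml_fit(inst$y, inst$K)
    b1 <- henderson_solve(inst$y, inst$K, vc, route = "henderson")
    b2 <- henderson_solve(inst$y, inst$K, vc, route = "vinverse")
    scale <- max(abs(c(b2$beta, b2$xi)))
    expect_lt(max(abs(c(b1$beta - b2$beta, b1$xi - b2$xi))) / scale, 1e-8)
  }
})

test_that("a printed 3-line toy solves identically by both routes", {
  K <- matrix(c(1.2, 0.5, -0.3,
                0.5, 0.9, 0.1,
                -0.3, 0.1, 0.9), 3, 3)
  y <- c(1.0, -0.5, 2.0)
  vc <- list(sigma_A2 = 0.8, sigma2 = 0.4)
  b1 <- henderson_solve(y, K, vc, route = "henderson")
  b2 <- henderson_solve(y, K, vc, route = "vinverse")
  expect_equal(b1$beta, b2$beta, tolerance = 1e-10)
  expect_equal(b1$xi, b2$xi, tolerance = 1e-10)
  # and the solution satisfies the block system
  lambda <- vc$sigma_A2 / vc$sigma2
  X <- matrix(1, 3, 1)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(3) + solve(K) / lambda))
  expect_equal(as.numeric(C %*% c(b1$beta, b1$xi)), c(sum(y), y),
               tolerance = 1e-8)
})

test_that("infinite shrinkage: xi -> 0 and beta -> OLS as lambda -> 0", {
  set.seed(5)
  inst <- random_instance(n = 25)
  vc <- list(sigma_A2 = 1e-10, sigma2 = var(inst$y))
  b <- henderson_solve(inst$y, inst$K, vc, route = "vinverse")
  expect_lt(max(abs(b$xi)), 1e-8)
  expect_equal(b$beta, mean(inst$y), tolerance = 1e-8)
})

test_that("intercept-only fits satisfy the GLS estimating equation", {
  set.seed(6)
  inst <- random_instance(n = 30)
  vc <- reml_fit(inst$y, inst$K)
  b <- henderson_solve(inst$y, inst$K, vc)
  # from the first block row: X'(y - X beta - xi) = 0
  expect_equal(sum(inst$y - b$beta - b$xi), 0, tolerance = 1e-6)
})

test_that("test rows with zero genomic covariance predict at the fixed effects", {
  set.seed(7)
  inst <- random_instance(n = 20)
  K <- inst$K
  K[20, -20] <- 0
  K[-20, 20] <- 0
  vc <- reml_fit(inst$y[-20], K[-20, -20])
  pred <- predict_holdout(inst$y, K, vc, test = 20)
  expect_equal(pred$xi2_hat, 0, tolerance = 1e-12)
  expect_equal(pred$y2_hat, pred$beta, tolerance = 1e-12)
})

test_that("a duplicated individual approaches its training BLUP as sigma2 -> floor", {
  set.seed(8)
  Z <- matrix(sample(c(-1, 1), 20 * 80, replace = TRUE), 20, 80)
  Z <- rbind(Z, Z[3, ]) # individual 21 is a genotype copy of individual 3
  K <- kinship(Z)
  y <- c(rnorm(20), 0)
  vc <- list(sigma_A2 = 1, sigma2 = 1e-5)
  pred <- predict_holdout(y, K, vc, test = 21)
  train_fit <- henderson_solve(y[1:20], K[1:20, 1:20], vc, route = "vinverse")
  expect_equal(pred$xi2_hat, unname(train_fit$xi[3]), tolerance = 1e-6)
})

test_that("holdout prediction rejects malformed index sets", {
  set.seed(9)
  inst <- random_instance(n = 10)
  vc <- list(sigma_A2 = 1, sigma2 = 1)
  expect_error(predict_holdout(inst$y, inst$K, vc, test = integer(0)), "empty")
  expect_error(predict_holdout(inst$y, inst$K, vc, test = c(1, 1)), "duplicates")
  expect_error(predict_holdout(inst$y, inst$K, vc, test = 11), "range")
  expect_error(predict_holdout(inst$y, inst$K, vc, test = 1:10), "Training set is empty")
})
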