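test_that("candidate sampling follows N(mean, sigma^2 C)", {
  st <- cmaes_init(numeric(6))
  expect_identical(st$popsize, 12L) # twice the parameter count
  # law of large numbers: sample mean near the distribution mean
  st$popsize <- 10000L
  X <- cmaes_ask(st, seed = 1)
  se <- st$sigma / sqrt(10000)
  expect_true(all(abs(rowMeans(X)) < 4 * se))
  expect_equal(apply(X, 1, sd), rep(st$sigma, 6), tolerance = 0.05)
  # vanishing step size: all candidates collapse onto the mean
  st2 <- cmaes_init(c(1, -2, 3), sigma0 = 1e-12)
  X2 <- cmaes_ask(st2, seed = 2)
  expect_equal(X2, matrix(c(1, -2, 3), 3, 6), tolerance = 1e-9)
})

test_that("CMA-ES minimizes the sphere function from an offset start", {
  d <- 6
  st <- cmaes_init(rep(5, d), sigma0 = 1)
  for (i in 1:200) {
    X <- cmaes_ask(st, seed = i)
    st <- cmaes_tell(st, X, colSums(X^2))
    if (sqrt(sum(st$mean^2)) < 1e-3) break
  }
  expect_lt(sqrt(sum(st$mean^2)), 1e-3)
})

test_that("rank-based updates are invariant to candidate order and move
           toward a dominant candidate", {
  set.seed(3)
  st <- cmaes_init(numeric(4), sigma0 = 0.5)
  X <- cmaes_ask(st, seed = 4)
  losses <- runif(ncol(X))
  s1 <- cmaes_tell(st, X, losses)
  perm <- sample(ncol(X))
  s2 <- cmaes_tell(st, X[, perm], losses[perm])
  expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
  expect_equal(s1$C, s2$C, tolerance = 1e-12)
  # one candidate far better than the rest pulls the mean toward it
  losses2 <- rep(1, ncol(X)); losses2[5] <- 0
  s3 <- cmaes_tell(st, X, losses2)
  d_before <- sqrt(sum((st$mean - X[, 5])^2))
  d_after <- sqrt(sum((s3$mean - X[, 5])^2))
  expect_lt(d_after, d_before)
  # no ranking information: the mean must not move
  s4 <- cmaes_tell(st, X, rep(0.7, ncol(X)))
  expect_identical(s4$mean, st$mean)
  expect_identical(s4$gen, st$gen + 1L)
})

test_that("the covariance stays symmetric positive semidefinite across
           generations", {
  set.seed(5)
  st <- cmaes_init(numeric(5), sigma0 = 0.3)
  for (i in 1:50) {
    X <- cmaes_ask(st, seed = 100 + i)
    st <- cmaes_tell(st, X, runif(ncol(X)))
    expect_equal(st$C, t(st$C), tolerance = 1e-12)
    expect_gt(min(eigen(st$C, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("the correlation matrix normalizes the covariance and masks
           degenerate components", {
  expect_equal(correlation_matrix(diag(3)), diag(3))
  C <- matrix(c(4, -2, -2, 9), 2, 2)
  R <- correlation_matrix(C)
  expect_equal(diag(R), c(1, 1))
  expect_equal(R[1, 2], -2 / 6)
  expect_equal(R, t(R))
  C0 <- diag(c(1, 0, 2))
  R0 <- correlation_matrix(C0)
  expect_true(all(is.na(R0[2, ])) && all(is.na(R0[, 2])))
  expect_equal(R0[1, 1], 1)
})

test_that("the optimizer recovers a known rule through the codec
           end-to-end", {
  # synthetic quadratic loss over the encoded pair-based space: no
  # simulation, exercises decode/encode + CMA-ES jointly
  theta_true <- c(-0.2, 0.1, 0.05, -0.3, log(25), log(60))
  loss_fn <- function(th) {
    r <- decode_theta(th, "small_poly")
    sum((encode_theta(r) - theta_true)^2)
  }
  st <- cmaes_init(encode_theta(init_quiescent("small_poly")), sigma0 = 0.5)
  for (i in 1:300) {
    X <- cmaes_ask(st, seed = 200 + i)
    st <- cmaes_tell(st, X, apply(X, 2, loss_fn))
    if (sqrt(sum((st$mean - theta_true)^2)) < 1e-2) break
  }
  expect_lt(sqrt(sum((st$mean - theta_true)^2)), 1e-2)
})

test_that("short meta-learning runs are reproducible and track the best
           candidate", {
  task <- quick_stability_task()
  m1 <- run_meta_learning(task, "small_poly", seed = 77, max_iter = 2)
  m2 <- run_meta_learning(task, "small_poly", seed = 77, max_iter = 2)
  expect_identical(m1$trajectory, m2$trajectory)
  expect_identical(m1$best_theta, m2$best_theta)
  expect_equal(nrow(m1$trajectory), 2)
  expect_lte(m1$best_candidate$loss, min(m1$trajectory$best_loss))
  expect_length(m1$best_rule, 1)
  expect_s3_class(m1$best_rule$ie, "small_poly_rule")
})
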