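test_that("parameter codecs round-trip and have the documented dimensions", {
  expect_identical(theta_length("small_poly"), 6L)
  expect_identical(theta_length("big_poly"), 21L)
  expect_identical(theta_length("mlp"), 11L)
  r1 <- small_poly_rule(-0.3, 0.2, 0.1, -0.05, tau_pre = 17, tau_post = 23)
  expect_equal(decode_theta(encode_theta(r1), "small_poly"), r1)
  th <- rnorm(21)
  r2 <- big_poly_rule(th)
  expect_equal(encode_theta(decode_theta(th, "big_poly")), th)
  r3 <- mlp_rule(w_pre = 1:4 / 10, b_pre = 0.5, w_post = -(1:4) / 10,
                 b_post = -0.5, learning_rate = 0.01, frozen_seed = 7L)
  expect_equal(decode_theta(encode_theta(r3), "mlp", frozen_seed = 7L), r3)
  # any real vector decodes to positive time constants
  r4 <- decode_theta(c(0, 0, 0, 0, -30, -30), "small_poly")
  expect_gt(r4$tau_pre, 0)
  expect_error(decode_theta(numeric(5), "small_poly"), "length")
})

test_that("single-event increments follow the printed rule forms", {
  r <- small_poly_rule(alpha = 0.5)
  expect_equal(small_poly_delta(r, "pre", x_post = 99), 0.5)
  expect_equal(small_poly_delta(small_poly_rule(), "post", x_pre = 3), 0)
  rk <- small_poly_rule(kappa = 2)
  expect_equal(small_poly_delta(rk, "pre", x_post = 0.25), 0.5)
  # big polynomial: all factors collapse to 1 when their amplitudes are 0
  rb <- big_poly_rule(c(3, rep(0, 20)))
  expect_equal(big_poly_delta(rb, "pre", w = 5, V_avg = -60, C_E = 2,
                              C_I = -1, x_long_pre = 4), 3)
  expect_equal(big_poly_delta(big_poly_rule(), "post", x_long_post = 2), 0)
  # separable factors multiply
  th <- numeric(21); th[1] <- 2; th[3] <- 0.5; th[10] <- 1
  rb2 <- big_poly_rule(th)
  expect_equal(big_poly_delta(rb2, "pre", w = 2, x_short_post = 3),
               2 * (1 + 0.5 * 2) * (1 + 3))
})

test_that("a post-then-pre spike pair weights the trace by the exponential
           kernel", {
  # post at t, pre 10 ms later, kappa = 1, tau_post = 10 ms: dw = exp(-1)
  r <- small_poly_rule(kappa = 1, tau_post = 10)
  res <- apply_rule_to_spike_train(r, pre_times = 20, post_times = 10,
                                   duration_ms = 50)
  expect_equal(res$w_final, exp(-1), tolerance = 1e-12)
  # traces jump by exactly 1 at a spike: two pre spikes dt apart with
  # gamma = 1 probe x_pre = exp(-dt/tau) after one spike
  r2 <- small_poly_rule(gamma = 1, tau_pre = 10)
  res2 <- apply_rule_to_spike_train(r2, pre_times = 10, post_times = 20,
                                    duration_ms = 50)
  expect_equal(res2$w_final, exp(-1), tolerance = 1e-12)
})

test_that("simultaneous pre and post spikes use the documented tie-break", {
  # pre at 0 ms, then coincident pre+post at 10 ms (tau_pre = 10):
  # second pre reads x_post = 0 (before the post bump), the post event
  # reads x_pre = exp(-1) (before the second pre bump)
  r <- small_poly_rule(alpha = 0.1, beta = 0.01, gamma = 1, kappa = 1,
                       tau_pre = 10, tau_post = 10)
  res <- apply_rule_to_spike_train(r, pre_times = c(0, 10), post_times = 10,
                                   duration_ms = 20)
  expect_equal(res$w_final, 2 * 0.1 + 0.01 + exp(-1), tolerance = 1e-12)
  expect_equal(small_poly_oracle(r, c(0, 10), 10), res$w_final,
               tolerance = 1e-12)
})

test_that("the big polynomial restricted to the pair-based submanifold
           reproduces pair-based trajectories", {
  set.seed(42)
  for (rep in 1:10) {
    a <- runif(1, -0.5, 0.5); b <- runif(1, -0.5, 0.5)
    g <- runif(1, -0.5, 0.5); k <- runif(1, -0.5, 0.5)
    if (abs(a) < 0.05) a <- 0.2
    if (abs(b) < 0.05) b <- -0.2
    small <- small_poly_rule(a, b, g, k, tau_pre = 10, tau_post = 10)
    th <- numeric(21)
    th[1] <- a; th[10] <- k / a   # pre:  a * (1 + (k/a) x_post_short)
    th[11] <- b; th[19] <- g / b  # post: b * (1 + (g/b) x_pre_short)
    big <- big_poly_rule(th)
    pre <- random_train(20, 500)
    post <- random_train(20, 500)
    rs <- apply_rule_to_spike_train(small, pre, post, 600)
    rb <- apply_rule_to_spike_train(big, pre, post, 600)
    expect_lt(max(abs(rs$w_after - rb$w_after)), 1e-10)
  }
})

test_that("the MLP rule is bounded, deterministic and zero when quiescent", {
  fz1 <- mlp_frozen_weights(5)
  fz2 <- mlp_frozen_weights(5)
  expect_identical(fz1, fz2)
  expect_identical(dim(fz1$W1), c(50L, 6L))
  expect_identical(dim(fz1$W2), c(4L, 50L))
  expect_true(all(abs(fz1$W1) <= 1 / sqrt(6)))
  expect_true(all(abs(fz1$W2) <= 1 / sqrt(50)))
  rq <- mlp_rule(frozen_seed = 5)
  set.seed(1)
  for (i in 1:20)
    expect_identical(mlp_delta(rq, "pre", rnorm(6), frozen = fz1), 0)
  r <- mlp_rule(w_pre = c(1, -2, 0.5, 3), b_pre = -1,
                w_post = c(0.1, 0.2, -0.3, 0.4), b_post = 2,
                learning_rate = 0.05, frozen_seed = 5)
  bound_pre <- abs(r$learning_rate) * (sum(abs(r$w_pre)) + abs(r$b_pre))
  bound_post <- abs(r$learning_rate) * (sum(abs(r$w_post)) + abs(r$b_post))
  set.seed(2)
  for (i in 1:50) {
    x <- rnorm(6, sd = 20)
    expect_lte(abs(mlp_delta(r, "pre", x, frozen = fz1)), bound_pre)
    expect_lte(abs(mlp_delta(r, "post", x, frozen = fz1)), bound_post)
    # same parameters, same frozen seed: identical output
    expect_identical(mlp_delta(r, "pre", x, frozen = fz1),
                     mlp_delta(r, "pre", x, frozen = fz2))
  }
})

test_that("weight bounds clip hard, idempotently, and reject bad configs", {
  expect_equal(apply_bounds(12, c(0, 10)), 10)
  expect_equal(apply_bounds(-0.3, c(0, 10)), 0)
  expect_equal(apply_bounds(5, c(0, 10)), 5)
  w <- runif(50, -5, 15)
  expect_identical(apply_bounds(apply_bounds(w)), apply_bounds(w))
  expect_error(apply_bounds(1, c(3, 2)), "lo <= hi")
  expect_error(apply_bounds(1, c(-1, 2)), ">= 0")
})

test_that("quiescent rules leave every weight exactly unchanged over a full
           episode", {
  net <- tiny_network("vogels", seed = 13, w = 0.5)
  for (space in c("small_poly", "big_poly", "mlp")) {
    asg <- rule_assignment(ie = init_quiescent(space),
                           ee = init_quiescent(space))
    res <- simulate_episode(net, asg, input = 20, duration_ms = 500,
                            input_seed = 14)
    expect_gt(res$n_spikes_exc, 0)
    expect_identical(res$w_final$ie, net$blocks$ie$w)
    expect_identical(res$w_final$ee, net$blocks$ee$w)
  }
})

test_that("weights respect their bounds after every update during an
           episode", {
  net <- tiny_network("vogels", seed = 15, w = 0.5)
  # violently potentiating and depressing rules
  asg <- rule_assignment(ie = small_poly_rule(alpha = 2, beta = -3),
                         bounds = c(0, 10))
  res <- simulate_episode(net, asg, input = 30, duration_ms = 1000,
                          input_seed = 16)
  expect_true(all(res$w_final$ie >= 0 & res$w_final$ie <= 10))
  expect_true(any(res$w_final$ie == 0) || any(res$w_final$ie == 10))
})

test_that("traces of a neuron firing at a steady rate converge to rate *
           tau in the mean", {
  # gamma = 1 makes each post event report x_pre; probe with regular post
  # spikes against a 20 Hz Poisson presynaptic train
  set.seed(17)
  rate <- 20; tau <- 50
  r <- small_poly_rule(gamma = 1, tau_pre = tau)
  pre <- sort(runif(rate * 20, 0, 20000))
  post <- seq(500, 20000, by = 100)
  res <- apply_rule_to_spike_train(r, pre, post, 20500)
  mean_x <- res$w_final / length(post)
  expected <- rate * tau / 1000
  expect_equal(mean_x, expected, tolerance = 0.15)
})

test_that("aux-dependent rules drive weight changes in live episodes within
           bounds", {
  net <- tiny_network("vogels", seed = 31, w = 0.5)
  th <- numeric(21); th[1] <- -0.02; th[11] <- 0.01; th[20] <- 0.5
  mlp <- mlp_rule(w_pre = c(0.5, -0.5, 0.2, 0.1), b_pre = 0.2,
                  w_post = c(-0.2, 0.3, 0.1, -0.4), b_post = -0.1,
                  learning_rate = 0.05, frozen_seed = 9)
  asg <- rule_assignment(ie = big_poly_rule(th), ee = mlp, bounds = c(0, 10))
  r1 <- simulate_episode(net, asg, input = 25, duration_ms = 1000,
                         input_seed = 32)
  r2 <- simulate_episode(net, asg, input = 25, duration_ms = 1000,
                         input_seed = 32)
  expect_false(r1$diverged)
  expect_identical(r1$w_final, r2$w_final)
  expect_false(identical(r1$w_final$ie, net$blocks$ie$w))
  expect_false(identical(r1$w_final$ee, net$blocks$ee$w))
  for (nm in c("ie", "ee"))
    expect_true(all(r1$w_final[[nm]] >= 0 & r1$w_final[[nm]] <= 10))
})

test_that("co-active rules consume consecutive segments of the candidate
           vector", {
  task <- quick_stability_task(blocks = c("ee", "ie"))
  th <- c(encode_theta(small_poly_rule(alpha = 0.001)),
          encode_theta(small_poly_rule(alpha = -0.001, tau_post = 100)))
  l <- evaluate_candidate(th, "small_poly", task, seed_base = 61)
  expect_true(is.finite(as.numeric(l)))
  expect_error(evaluate_candidate(th[1:6], "small_poly", task,
                                  seed_base = 61), "length")
})
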