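test_that("pairing-protocol curves match the exponential kernel closed
           form", {
  A <- 0.8; tau <- 15
  r <- small_poly_rule(gamma = A, tau_pre = tau)
  grid <- seq(-40, 40, by = 5)
  cv <- pre_post_curve(r, dt_grid = grid)
  expected <- ifelse(grid > 0, A * exp(-grid / tau), 0)
  # dt = 0: tie-break reads the pre trace before its bump -> 0
  expected[grid == 0] <- 0
  expect_equal(cv$dw, expected, tolerance = 1e-12)
  # pre-side kernel mirrors with kappa
  r2 <- small_poly_rule(kappa = A, tau_post = tau)
  cv2 <- pre_post_curve(r2, dt_grid = grid)
  expect_equal(cv2$dw, ifelse(grid < 0, A * exp(grid / tau), 0),
               tolerance = 1e-12)
})

test_that("quiescent rules give identically zero curves in every space", {
  grid <- seq(-20, 20, by = 10)
  for (space in c("small_poly", "big_poly", "mlp")) {
    cv <- pre_post_curve(init_quiescent(space), dt_grid = grid)
    expect_identical(cv$dw, rep(0, length(grid)))
  }
})

test_that("symmetric parameters give a curve symmetric in delta t", {
  r <- small_poly_rule(alpha = 0.1, beta = 0.1, gamma = 0.4, kappa = 0.4,
                       tau_pre = 20, tau_post = 20)
  grid <- seq(-30, 30, by = 3)
  cv <- pre_post_curve(r, dt_grid = grid)
  expect_equal(cv$dw, rev(cv$dw), tolerance = 1e-12)
})

test_that("aux-dependent spaces record their clamps and respond to them", {
  th <- numeric(21); th[1] <- 1; th[5] <- 0.01 # pre factor with <V> term
  r <- big_poly_rule(th)
  cv1 <- pre_post_curve(r, dt_grid = 0:2, V_avg = -60)
  cv2 <- pre_post_curve(r, dt_grid = 0:2, V_avg = 0)
  expect_equal(unique(cv1$dw), 1 + 0.01 * (-60))
  expect_equal(unique(cv2$dw), 1)
  expect_equal(attr(cv1, "protocol")$clamps[["V_avg"]], -60)
})

test_that("episode summaries report rates, regularity, silence and weight
           saturation", {
  net <- tiny_network("vogels", seed = 23, w = 0.5)
  res <- simulate_episode(net, input = 25, duration_ms = 2000,
                          input_seed = 24, record_spikes = TRUE)
  sm <- episode_summary(res)
  dur_s <- 2
  expect_equal(sm$rate_hz[["exc"]],
               nrow(res$raster_exc) / (net$n_exc * dur_s))
  expect_true(sm$fraction_silent[["exc"]] >= 0 &&
                sm$fraction_silent[["exc"]] <= 1)
  # a Poisson raster has ISI CV ~ 1, a clock ~ 0
  pois <- poisson_spikes(50, 20, 20000, seed = 25)
  fake <- res
  fake$raster_exc <- pois
  fake$raster_inh <- pois
  smp <- episode_summary(fake)
  expect_equal(smp$isi_cv[["exc"]], 1, tolerance = 0.12)
  clock <- structure(
    data.frame(id = rep(1:5, each = 50),
               time_ms = rep(seq(10, 500, by = 10), times = 5)),
    n_neurons = 5L, duration_ms = 500,
    class = c("spike_raster", "data.frame"))
  fake$raster_exc <- clock
  expect_lt(episode_summary(fake)$isi_cv[["exc"]], 0.01)
  # saturation fraction
  fake$w_final$ie <- rep(10, 20)
  expect_equal(episode_summary(fake)$weights["ie", "frac_saturated"], 1)
})

test_that("summary metrics are invariant under neuron relabeling", {
  net <- tiny_network("vogels", seed = 26, w = 0.5)
  res <- simulate_episode(net, input = 25, duration_ms = 1000,
                          input_seed = 27, record_spikes = TRUE)
  s1 <- episode_summary(res)
  perm <- sample(net$n_exc)
  res2 <- res
  res2$raster_exc$id <- perm[res2$raster_exc$id]
  s2 <- episode_summary(res2)
  expect_equal(s1$rate_hz, s2$rate_hz)
  expect_equal(s1$isi_cv, s2$isi_cv, tolerance = 1e-12)
  expect_equal(s1$fraction_silent, s2$fraction_silent)
})

test_that("rules serialize to JSON and reload identically", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  r <- small_poly_rule(-0.1, 0.2, 0.3, -0.4, tau_pre = 12, tau_post = 34)
  write_rule(r, tmp, bounds = c(0, 8))
  r2 <- read_rule(tmp)
  expect_equal(r2, r, ignore_attr = TRUE)
  expect_equal(attr(r2, "bounds"), c(0, 8))
  rm <- mlp_rule(w_pre = 1:4 / 7, b_pre = 0.3, w_post = 4:1 / 9,
                 b_post = -0.2, learning_rate = 0.02, frozen_seed = 11L)
  write_rule(rm, tmp)
  rm2 <- read_rule(tmp)
  expect_equal(rm2, rm, ignore_attr = TRUE)
  expect_identical(rm2$frozen_seed, 11L)
})
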