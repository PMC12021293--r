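test_that("connectivity is Bernoulli sparse at the configured densities", {
  # full-scale fixed-threshold variant: 2% recurrent, 5% input
  cfg <- topology_config("vogels", "full")
  net <- build_network("vogels", cfg, seed = 1)
  for (nm in c("ee", "ie")) {
    b <- net$blocks[[nm]]
    n_pairs <- b$npre * (b$npost - if (nm == "ee") 1 else 0)
    p_hat <- length(b$pre) / n_pairs
    se <- sqrt(0.02 * 0.98 / n_pairs)
    expect_lt(abs(p_hat - 0.02), 4 * se)
  }
  b <- net$blocks$xe
  p_hat <- length(b$pre) / (b$npre * b$npost)
  expect_lt(abs(p_hat - 0.05), 4 * sqrt(0.05 * 0.95 / (b$npre * b$npost)))
  # adaptive-threshold variant: 10% recurrent at full scale
  cfg2 <- topology_config("zenke", "full", n_exc = 512L, n_inh = 128L,
                          n_ext = 500L)
  net2 <- build_network("zenke", cfg2, seed = 2)
  b2 <- net2$blocks$ee
  p_hat2 <- length(b2$pre) / (512 * 511)
  expect_lt(abs(p_hat2 - 0.10), 4 * sqrt(0.1 * 0.9 / (512 * 511)))
  # no self-connections, no duplicate pairs
  for (nm in c("ee", "ii")) {
    b <- net2$blocks[[nm]]
    expect_false(any(b$pre == b$post))
    expect_false(anyDuplicated(paste(b$pre, b$post)) > 0)
  }
})

test_that("network construction is deterministic and validates its inputs", {
  cfg <- topology_config("vogels", "desk")
  n1 <- build_network("vogels", cfg, seed = 9)
  n2 <- build_network("vogels", cfg, seed = 9)
  expect_identical(n1$blocks, n2$blocks)
  n3 <- build_network("vogels", cfg, seed = 10)
  expect_false(identical(n1$blocks$ee$w, n3$blocks$ee$w))
  # an empty required block is a configuration error
  bad <- topology_config("vogels", "desk", n_exc = 4L, n_inh = 2L,
                         n_ext = 5L, p_rec = 0.01)
  expect_error(build_network("vogels", bad, seed = 1), "zero connections")
  expect_error(topology_config("vogels", p_rec = 0), "densities")
  expect_error(vogels_neuron_params(V_th = -90), "E_inh < V_rest")
  expect_error(zenke_neuron_params(a_frac = 1.2), "a_frac")
})

test_that("membrane at rest with no input stays exactly at rest", {
  net <- tiny_network("vogels", seed = 3)
  res <- simulate_episode(net, input = 0, duration_ms = 100, record_v = 1)
  expect_true(all(res$v_trace == net$params$V_rest))
  expect_identical(res$n_spikes_exc + res$n_spikes_inh, 0)
})

test_that("conductances decay exponentially and the membrane relaxes to the
           conductance fixed point", {
  net <- tiny_network("vogels", seed = 4)
  st <- init_network_state(net)
  st$g_AMPA[1] <- 2; st$g_GABA[1] <- 1
  out <- step_network(st, net, integer(0), dt_ms = 0.1)
  expect_equal(out$state$g_AMPA[1], 2 * exp(-0.1 / 5), tolerance = 1e-12)
  expect_equal(out$state$g_GABA[1], 1 * exp(-0.1 / 10), tolerance = 1e-12)
  # near-constant conductances (huge decay constants): V -> algebraic fixed
  # point (V_rest + gE*E_exc + gI*E_inh) / (1 + gE + gI)
  prm <- vogels_neuron_params(tau_AMPA = 1e9, tau_GABA = 1e9, V_th = -1)
  netc <- tiny_network("vogels", seed = 4)
  netc$params <- prm
  st <- init_network_state(netc)
  gE <- 0.5; gI <- 0.3
  st$g_AMPA[] <- gE; st$g_GABA[] <- gI
  for (i in 1:3000) st <- step_network(st, netc, integer(0), 0.1)$state
  vstar <- (prm$V_rest + gE * prm$E_exc + gI * prm$E_inh) / (1 + gE + gI)
  expect_equal(st$V[1], vstar, tolerance = 1e-6)
})

test_that("no neuron violates the absolute refractory period", {
  net <- tiny_network("vogels", seed = 5, w = 0.8)
  res <- simulate_episode(net, input = 40, duration_ms = 2000,
                          input_seed = 6, record_spikes = TRUE)
  expect_gt(nrow(res$raster_exc), 100) # the test needs activity
  min_isi <- min(vapply(split(res$raster_exc$time_ms, res$raster_exc$id),
                        function(tt) if (length(tt) < 2) Inf
                        else min(diff(sort(tt))), numeric(1)))
  expect_gte(min_isi, net$params$tau_ref)
})

test_that("the adaptive threshold jumps at a spike and relaxes
           exponentially", {
  net <- tiny_network("zenke", seed = 6, w = 1e-6)
  p <- net$params
  st <- init_network_state(net)
  st$V[1] <- -45 # above the baseline threshold: spikes this step
  out <- step_network(st, net, integer(0), 0.1)
  expect_identical(out$spikes, 1L)
  expect_equal(out$state$V[1], p$V_reset)
  th0 <- out$state$V_th[1] - p$V_th_base
  expect_equal(th0, p$V_th_spike, tolerance = 1e-9)
  st <- out$state
  for (i in 1:200) st <- step_network(st, net, integer(0), 0.1)$state
  expect_equal(st$V_th[1] - p$V_th_base, th0 * exp(-20 / p$tau_th),
               tolerance = 1e-9)
})

test_that("the reference stepper and the compiled integrator emit identical
           spike trains", {
  for (variant in c("vogels", "zenke")) {
    net <- tiny_network(variant, seed = 7, w = 0.5)
    inp <- poisson_spikes(50, 50, 200, seed = 8)
    steps <- as.integer(round(inp$time_ms / 0.1)) - 1L
    o <- order(steps, inp$id)
    sched <- list(step = steps[o], id = inp$id[o], n_ext = 50L,
                  duration_ms = 200, dt_ms = 0.1)
    res <- simulate_episode(net, input = sched, duration_ms = 200,
                            record_spikes = TRUE)
    cpp <- rbind(cbind(res$raster_exc$id, res$raster_exc$time_ms),
                 cbind(res$raster_inh$id + net$n_exc,
                       res$raster_inh$time_ms))
    cpp <- cpp[order(cpp[, 2], cpp[, 1]), , drop = FALSE]
    st <- init_network_state(net)
    ref <- NULL
    for (s in 0:1999) {
      out <- step_network(st, net, inp$id[steps == s], 0.1)
      st <- out$state
      if (length(out$spikes))
        ref <- rbind(ref, cbind(out$spikes, (s + 1) * 0.1))
    }
    ref <- ref[order(ref[, 2], ref[, 1]), , drop = FALSE]
    expect_gt(nrow(cpp), 10)
    expect_equal(unname(cpp), unname(ref), tolerance = 1e-12)
  }
})

test_that("identical seeds give bit-identical episodes", {
  net <- tiny_network("vogels", seed = 11, w = 0.5)
  r1 <- simulate_episode(net, input = 20, duration_ms = 500,
                         input_seed = 12, record_spikes = TRUE)
  r2 <- simulate_episode(net, input = 20, duration_ms = 500,
                         input_seed = 12, record_spikes = TRUE)
  expect_identical(r1$raster_exc, r2$raster_exc)
  expect_identical(r1$rates, r2$rates)
  expect_identical(r1$w_final, r2$w_final)
})
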