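# Independent event-driven oracle for the pair-based polynomial rule:
# processes the merged spike sequence chronologically, decaying both traces
# by exact exponentials between events and accumulating the closed-form
# increments.  Shares no code with the step-based integrator.
small_poly_oracle <- function(rule, pre_times, post_times) {
  ev <- rbind(
    if (length(pre_times)) data.frame(t = pre_times, pre = TRUE),
    if (length(post_times)) data.frame(t = post_times, pre = FALSE))
  # same-time tie-break: pre before post
  ev <- ev[order(ev$t, !ev$pre), ]
  x_pre <- 0; x_post <- 0; t_last <- 0; dw <- 0
  i <- 1
  while (i <= nrow(ev)) {
    t <- ev$t[i]
    x_pre <- x_pre * exp(-(t - t_last) / rule$tau_pre)
    x_post <- x_post * exp(-(t - t_last) / rule$tau_post)
    t_last <- t
    # all events at this time read the traces before any increment
    j <- i
    while (j <= nrow(ev) && ev$t[j] == t) j <- j + 1
    here <- ev[i:(j - 1), ]
    for (k in seq_len(nrow(here))) {
      dw <- dw + if (here$pre[k]) rule$alpha + rule$kappa * x_post
                 else rule$beta + rule$gamma * x_pre
    }
    x_pre <- x_pre + sum(here$pre)
    x_post <- x_post + sum(!here$pre)
    i <- j
  }
  dw
}

# random two-neuron spike trains on the integration grid
random_train <- function(n_spikes, duration_ms, dt_ms = 0.1) {
  sort(sample.int(round(duration_ms / dt_ms), n_spikes)) * dt_ms
}

# small network that builds and simulates quickly
tiny_network <- function(variant = "vogels", seed = 1, w = 0.4) {
  cfg <- topology_config(variant, "desk", n_exc = 40, n_inh = 10,
                         n_ext = 50,
                         w_mean = list(ee = w, ei = w, ie = w, ii = w,
                                       xe = w, xi = w))
  build_network(variant, cfg, seed = seed)
}

# fast stability task used by unit tests (scaled-down episodes)
quick_stability_task <- function(...) {
  stability_task(duration_ms = 2000, eval_fraction = 0.5,
                 eval_window_ms = 500, n_trials = 2, ...)
}
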