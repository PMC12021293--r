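#' Simulate one episode of a plastic recurrent spiking network
#'
#' Integrates the network with forward Euler at `dt_ms` (0.1 ms default)
#' while external Poisson events drive it and the assigned plasticity rules
#' update weights at spike events.  Spike effects are applied at the end of
#' the step in which the spike occurs; the membrane update uses start-of-step
#' conductances.  Pre-triggered weight updates are applied before
#' post-triggered ones within a step, and a spiking neuron's traces are read
#' before their +1 increment.
#'
#' @param network An [build_network()] result.
#' @param assignment A [rule_assignment()] or `NULL` (all synapses static).
#' @param input Input schedule: either `NULL` (constant-rate Poisson input at
#'   the topology's `r_ext`), a single rate in Hz, or a schedule produced by
#'   [make_familiarity_protocol()].
#' @param duration_ms Episode duration (ms), a multiple of `dt_ms`.
#' @param dt_ms Integration step (ms).
#' @param rate_bin_ms Width of the tumbling windows of the recorded
#'   population-rate series.
#' @param eval_windows Optional K x 2 matrix of `[start, end)` times (ms);
#'   mean excitatory rates over these windows are returned in `eval_rates`.
#' @param freeze_after_ms Plasticity is disabled from this time on (used to
#'   probe a learned state without further learning).
#' @param record_spikes Record the full spike raster (otherwise only summary
#'   statistics are kept).
#' @param record_v Optional global neuron index (1-based, E first) whose
#'   membrane potential is recorded every step.
#' @param n_weight_samples Number of weight-summary samples per plastic
#'   block across the episode.
#' @param input_seed Optional seed for the internally generated Poisson
#'   input (ignored when `input` is a pre-built schedule).
#'
#' @return An `episode_result`: population-rate series, optional rasters,
#'   per-window evaluation rates, final weights and weight-trace summaries
#'   per block, spike counts, and a divergence flag (non-finite dynamics;
#'   flagged episodes are penalty-capped by the task losses).
#' @export
#' @examples
#' net <- build_network("vogels", topology_config("vogels", "desk"), seed = 1)
#' res <- simulate_episode(net, duration_ms = 500, input_seed = 1)
#' res
simulate_episode <- function(network, assignment = NULL, input = NULL,
                             duration_ms = 1000, dt_ms = 0.1,
                             rate_bin_ms = 100, eval_windows = NULL,
                             freeze_after_ms = Inf, record_spikes = TRUE,
                             record_v = NULL, n_weight_samples = 50,
                             input_seed = NULL) {
  stopifnot(inherits(network, "snn_network"))
  n_steps <- as.integer(round(duration_ms / dt_ms))
  if (abs(n_steps * dt_ms - duration_ms) > 1e-9)
    stop("duration_ms must be a multiple of dt_ms")
  if (is.null(assignment)) assignment <- rule_assignment()
  stopifnot(inherits(assignment, "rule_assignment"))

  if (is.null(input) || is.numeric(input)) {
    rate <- if (is.null(input)) network$config$r_ext else input
    if (!is.null(input_seed)) set.seed(as.integer(input_seed))
    input <- .input_schedule_constant(network$n_ext, rate, duration_ms,
                                      dt_ms)
  }
  if (input$dt_ms != dt_ms) stop("input schedule dt does not match dt_ms")
  if (input$n_ext != network$n_ext)
    stop("input schedule size does not match the network's input population")

  blocks <- lapply(names(network$blocks), function(nm) {
    rule <- if (nm %in% c("xe", "xi")) NULL else assignment$rules[[nm]]
    bd <- if (is.null(rule)) c(0, 10) else assignment$bounds[[nm]]
    .block_for_cpp(network$blocks[[nm]], rule, bd)
  })
  names(blocks) <- names(network$blocks)

  ew <- if (is.null(eval_windows)) matrix(numeric(0), ncol = 2)
        else as.matrix(eval_windows)
  res <- sim_episode_cpp(
    variant = if (network$variant == "zenke") 1L else 0L,
    prm = .params_for_cpp(network$params),
    n_exc = network$n_exc, n_inh = network$n_inh, blocks = blocks,
    ext_step = as.integer(input$step), ext_id = as.integer(input$id),
    n_steps = n_steps, dt = dt_ms, rate_bin_ms = rate_bin_ms,
    eval_windows_ms = ew, freeze_after_ms = freeze_after_ms,
    record_spikes = record_spikes,
    record_v = if (is.null(record_v)) -1L else as.integer(record_v) - 1L,
    n_weight_samples = as.integer(n_weight_samples))

  rates <- data.frame(
    time_ms = (seq_len(nrow(res$rates)) - 0.5) * res$rate_bin_ms,
    rate_exc = res$rates[, 1], rate_inh = res$rates[, 2])
  out <- list(rates = rates, eval_rates = as.numeric(res$eval_rates),
              w_final = res$w_final, w_stats = res$w_stats,
              diverged = isTRUE(res$diverged),
              n_spikes_exc = res$n_spikes_exc,
              n_spikes_inh = res$n_spikes_inh,
              duration_ms = duration_ms, dt_ms = dt_ms,
              n_exc = network$n_exc, n_inh = network$n_inh)
  if (record_spikes) {
    isE <- res$raster_id <= network$n_exc
    out$raster_exc <- .spike_raster(res$raster_id[isE],
                                    (res$raster_step[isE] + 1) * dt_ms,
                                    network$n_exc, duration_ms)
    out$raster_inh <- .spike_raster(res$raster_id[!isE] - network$n_exc,
                                    (res$raster_step[!isE] + 1) * dt_ms,
                                    network$n_inh, duration_ms)
  }
  if (!is.null(record_v)) out$v_trace <- res$v_trace
  structure(out, class = "episode_result")
}

#' @export
print.episode_result <- function(x, ...) {
  cat(sprintf(
    "<episode_result: %.0f ms, mean E rate %.2f Hz, mean I rate %.2f Hz%s>\n",
    x$duration_ms, mean(x$rates$rate_exc), mean(x$rates$rate_inh),
    if (x$diverged) ", DIVERGED" else ""))
  invisible(x)
}

#' Population firing rate from a spike raster
#'
#' Spike count per window divided by `n_neurons * window`, over tumbling
#' windows (default) or windows sliding by `step_ms`.
#'
#' @param raster A `spike_raster`.
#' @param window_ms Window width (ms), > 0.
#' @param step_ms Stride between window starts; equal to `window_ms`
#'   (tumbling) by default.
#' @return Data frame with window start `time_ms` and `rate_hz`.
#' @export
#' @examples
#' r <- poisson_spikes(200, 10, 1000, seed = 1)
#' mean(population_rate(r, 50)$rate_hz) # ~10 Hz
population_rate <- function(raster, window_ms, step_ms = window_ms) {
  stopifnot(inherits(raster, "spike_raster"), window_ms > 0, step_ms > 0)
  n <- attr(raster, "n_neurons")
  if (is.null(n) || n == 0) stop("raster has an empty population")
  dur <- attr(raster, "duration_ms")
  starts <- seq(0, dur - window_ms, by = step_ms)
  cnt <- vapply(starts, function(s)
    sum(raster$time_ms > s & raster$time_ms <= s + window_ms), numeric(1))
  data.frame(time_ms = starts, rate_hz = cnt / (n * window_ms / 1000))
}

# ---------------------------------------------------------------------------
# transparent single-step reference integrator (same scheme as the compiled
# core; used for inspection and as an independent cross-check in tests)

#' Initialize the dynamic state of a network at rest
#'
#' @param network An [build_network()] result.
#' @return A `network_state` list: membrane potentials at `V_rest`, all
#'   conductances zero, thresholds at base, refractory clocks zero.
#' @export
init_network_state <- function(network) {
  n <- network$n_exc + network$n_inh
  p <- network$params
  st <- list(V = rep(p$V_rest, n), g_AMPA = numeric(n), g_GABA = numeric(n),
             t_ms = 0)
  if (network$variant == "zenke") {
    st$g_NMDA <- numeric(n)
    st$V_th <- rep(p$V_th_base, n)
  } else {
    st$refr <- integer(n)
  }
  structure(st, class = "network_state")
}

#' Advance a network state by one Euler step (reference implementation)
#'
#' Plain-R mirror of one step of the compiled integrator, without
#' plasticity: forward-Euler membrane update from start-of-step
#' conductances, threshold crossing and reset, exact exponential conductance
#' decay (Euler NMDA relaxation), then end-of-step delivery of this step's
#' spikes.  Given identical inputs it reproduces the compiled core's spike
#' times bit for bit.
#'
#' @param state A [init_network_state()] state.
#' @param network The network the state belongs to.
#' @param input_events Integer ids of external input neurons spiking during
#'   this step (may be empty).
#' @param dt_ms Step size (ms).
#' @return List with the updated `state` and `spikes`, the global indices
#'   (E first) of neurons that fired.
#' @export
step_network <- function(state, network, input_events = integer(0),
                         dt_ms = 0.1) {
  p <- network$params
  zenke <- network$variant == "zenke"
  n <- length(state$V)
  V <- state$V; gA <- state$g_AMPA; gG <- state$g_GABA
  gE <- if (zenke) p$a_frac * gA + (1 - p$a_frac) * state$g_NMDA else gA
  th <- if (zenke) state$V_th else rep(p$V_th, n)
  act <- if (zenke) rep(TRUE, n) else state$refr == 0
  Vn <- V + dt_ms / p$tau_m *
    (-(V - p$V_rest) - gE * (V - p$E_exc) - gG * (V - p$E_inh))
  V[act] <- Vn[act]
  if (!zenke) {
    state$refr[!act] <- state$refr[!act] - 1L
    V[!act] <- p$V_rest
  }
  spikes <- which(act & V >= th)
  if (zenke) {
    V[spikes] <- p$V_reset
  } else {
    V[spikes] <- p$V_rest
    state$refr[spikes] <- as.integer(round(p$tau_ref / dt_ms))
  }
  if (zenke) {
    state$g_NMDA <- state$g_NMDA + dt_ms / p$tau_NMDA * (gA - state$g_NMDA)
    state$V_th <- p$V_th_base +
      (state$V_th - p$V_th_base) * exp(-dt_ms / p$tau_th)
    state$V_th[spikes] <- state$V_th[spikes] + p$V_th_spike
  }
  gA <- gA * exp(-dt_ms / p$tau_AMPA)
  gG <- gG * exp(-dt_ms / p$tau_GABA)
  deliver <- function(block, sources, offset_pre = 0L) {
    hit <- block$pre %in% sources
    if (!any(hit)) return(NULL)
    post <- block$post[hit] + if (block$post_pop == "inh") network$n_exc else 0L
    list(post = post, w = block$w[hit], exc = block$pre_pop != "inh")
  }
  srcs <- list(
    list(ids = input_events, blocks = c("xe", "xi"), loc = input_events),
    list(ids = spikes[spikes <= network$n_exc], blocks = c("ee", "ei")),
    list(ids = spikes[spikes > network$n_exc] - network$n_exc,
         blocks = c("ie", "ii")))
  for (sc in srcs) {
    if (length(sc$ids) == 0) next
    for (bn in sc$blocks) {
      d <- deliver(network$blocks[[bn]], sc$ids)
      if (is.null(d)) next
      for (k in seq_along(d$post)) {
        if (d$exc) gA[d$post[k]] <- gA[d$post[k]] + d$w[k]
        else gG[d$post[k]] <- gG[d$post[k]] + d$w[k]
      }
    }
  }
  state$V <- V; state$g_AMPA <- gA; state$g_GABA <- gG
  state$t_ms <- state$t_ms + dt_ms
  list(state = state, spikes = spikes)
}

# ---------------------------------------------------------------------------

#' Apply a plasticity rule to a prescribed pre/post spike-train pair
#'
#' Runs the step-based integrator's plasticity machinery on a single synapse
#' whose pre- and postsynaptic spike times are given, with the
#' membrane-dependent auxiliary variables clamped.  Traces decay by exact
#' exponentials, so for pair-based rules the cumulative weight change equals
#' the event-driven closed form.
#'
#' @param rule A `plasticity_rule`.
#' @param pre_times,post_times Spike times (ms), non-negative.
#' @param duration_ms Train duration (ms).
#' @param dt_ms Step size (ms); spikes are snapped to steps.
#' @param w0 Initial weight.
#' @param bounds Weight bounds `c(lo, hi)`.
#' @param clamps Named values of the clamped auxiliary variables
#'   (`V_avg` in mV, `C_E`, `C_I`), used by the separable-polynomial and MLP
#'   spaces.
#' @return List with `w_final`, per-event weights `w_after` and event times
#'   `event_time_ms`.
#' @export
#' @examples
#' r <- small_poly_rule(gamma = 0.5, tau_pre = 10)
#' apply_rule_to_spike_train(r, pre_times = 10, post_times = 20,
#'                           duration_ms = 50)$w_final
apply_rule_to_spike_train <- function(rule, pre_times, post_times,
                                      duration_ms, dt_ms = 0.1, w0 = 0,
                                      bounds = c(-Inf, Inf),
                                      clamps = c(V_avg = 0, C_E = 0,
                                                 C_I = 0)) {
  sp <- rule_space(rule)
  space <- switch(sp, small_poly = 1L, big_poly = 2L, mlp = 3L)
  theta <- switch(sp,
    small_poly = c(rule$alpha, rule$beta, rule$gamma, rule$kappa),
    big_poly = rule$theta,
    mlp = encode_theta(rule))
  W1 <- W2 <- NULL
  if (sp == "mlp") {
    fz <- mlp_frozen_weights(rule$frozen_seed)
    W1 <- fz$W1; W2 <- fz$W2
  }
  n_steps <- as.integer(round(duration_ms / dt_ms))
  # one spike per neuron per bin: coincident same-train spikes collapse
  snap <- function(tt) sort(unique(as.integer(round(tt / dt_ms))))
  res <- forced_train_cpp(space, theta, snap(pre_times), snap(post_times),
                          n_steps, dt_ms, w0, bounds[1], bounds[2],
                          c(clamps[["V_avg"]], clamps[["C_E"]],
                            clamps[["C_I"]]),
                          if (sp == "small_poly") rule$tau_pre else 10,
                          if (sp == "small_poly") rule$tau_post else 10,
                          W1, W2)
  list(w_final = res$w_final, w_after = res$w_after,
       event_time_ms = res$event_step * dt_ms)
}
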