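#' Deterministic seed ladder
#'
#' Folds a master seed with integer indices into a derived seed in
#' `[1, 2^31 - 2]`, so that every trial / candidate / iteration gets a
#' distinct, reproducible stream.
#'
#' @param seed Master seed.
#' @param ... Integer indices (iteration, candidate, trial, ...).
#' @return A derived integer seed.
#' @export
derive_seed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (idx in c(...)) x <- (x * 48271 + as.double(idx) + 1) %% 2147483647
  as.integer(max(1, x))
}

# L1 norm of the regularized amplitudes of an encoded vector: time-constant
# entries (log tau, small polynomial space) are excluded.
.l1_amplitudes <- function(theta, space) {
  if (space == "small_poly") {
    k <- length(theta) / 6
    sum(abs(theta[rep(seq_len(k) - 1, each = 4) * 6 + 1:4]))
  } else {
    sum(abs(theta))
  }
}

#' Firing-rate homeostasis task
#'
#' Inner-loop objective: with the configured blocks plastic, the excitatory
#' population rate must settle at `target_rate`.  Each trial randomizes the
#' external input rate, the per-block mean initial weights and the
#' connectivity, so surviving rules work across networks rather than for one
#' draw.
#'
#' @param variant Network variant (`"vogels"` by default, matching the
#'   original stability experiments).
#' @param scale Topology scale (`"desk"` or `"full"`).
#' @param blocks Character vector of plastic blocks (subset of
#'   `c("ee", "ei", "ie", "ii")`); a candidate vector decodes to one rule per
#'   block (co-active rules are concatenated).
#' @param target_rate Target excitatory population rate (Hz).
#' @param duration_ms Training episode duration (ms); 60 s at full scale,
#'   10 s on the desk preset used here.
#' @param eval_fraction Final fraction of the episode scored by the loss.
#' @param eval_window_ms Width of the tumbling evaluation windows (ms).
#' @param ext_rate_range Per-trial external-rate randomization (Hz).
#' @param w_mean_range Per-trial range of the mean initial weight per block.
#' @param bounds Weight bounds for plastic blocks.
#' @param lambda_l1 L1 regularization weight on the rule amplitudes.
#' @param penalty_cap Loss assigned to diverged episodes; ten times the loss
#'   of an all-silent network, so it dominates every regular loss.
#' @param n_trials Default number of randomized trials per candidate
#'   (between 4 and 10).
#' @param dt_ms Integration step (ms).
#' @return A `task_spec` of kind `"stability"`.
#' @export
stability_task <- function(variant = "vogels", scale = "desk",
                           blocks = "ie", target_rate = 10,
                           duration_ms = if (scale == "desk") 10000 else 60000,
                           eval_fraction = 0.5, eval_window_ms = 500,
                           ext_rate_range = c(4, 10),
                           w_mean_range = c(0.05, 0.5), bounds = c(0, 10),
                           lambda_l1 = 0.01, penalty_cap = 10,
                           n_trials = 4, dt_ms = 0.1) {
  stopifnot(all(blocks %in% c("ee", "ei", "ie", "ii")), length(blocks) >= 1,
            duration_ms > 0, target_rate > 0,
            n_trials >= 1, eval_fraction > 0, eval_fraction <= 1)
  structure(list(kind = "stability", variant = variant, scale = scale,
                 blocks = blocks, target_rate = target_rate,
                 duration_ms = duration_ms, eval_fraction = eval_fraction,
                 eval_window_ms = eval_window_ms,
                 ext_rate_range = ext_rate_range,
                 w_mean_range = w_mean_range, bounds = bounds,
                 lambda_l1 = lambda_l1, penalty_cap = penalty_cap,
                 n_trials = n_trials, dt_ms = dt_ms),
            class = "task_spec")
}

#' Familiarity-detection task
#'
#' A subset of input neurons (the familiar stimulus) is presented repeatedly
#' while plasticity is on; after a break, a disjoint novel subset and then
#' the familiar subset are presented with plasticity frozen.  Success means
#' a higher excitatory response to the familiar probe than to the novel one.
#'
#' @inheritParams stability_task
#' @param variant Network variant (`"zenke"` by default, matching the
#'   original familiarity experiments).
#' @param stim_fraction Fraction of input neurons per stimulus subset.
#' @param stim_multiplier Stimulus rate as a multiple of the background
#'   rate (> 1).
#' @param n_reps Number of familiar-stimulus repetitions during training.
#' @param present_ms,isi_ms Presentation length and inter-stimulus interval.
#' @param break_ms Background-only break between training and probes.
#' @param probe_ms Probe presentation length (plasticity frozen).
#' @param margin Required familiar-minus-novel response margin (Hz) of the
#'   hinge loss.
#' @param rate_band Plausible mean-excitatory-rate band (Hz); rates outside
#'   it are penalized.
#' @param penalty_cap Loss of diverged episodes; ten times the all-silent
#'   loss (hinge 1 + band penalty 1).
#' @return A `task_spec` of kind `"familiarity"`.
#' @export
familiarity_task <- function(variant = "zenke", scale = "desk",
                             blocks = "ie", stim_fraction = 0.1,
                             stim_multiplier = 4, n_reps = 10,
                             present_ms = 1000, isi_ms = 0, break_ms = 2000,
                             probe_ms = 1000, margin = 5,
                             rate_band = c(2, 30),
                             ext_rate_range = c(4, 10),
                             w_mean_range = c(0.05, 0.5), bounds = c(0, 10),
                             lambda_l1 = 0.01, penalty_cap = 20,
                             n_trials = 4, dt_ms = 0.1) {
  stopifnot(all(blocks %in% c("ee", "ei", "ie", "ii")),
            stim_multiplier > 1, stim_fraction > 0, stim_fraction <= 0.5,
            n_reps >= 1, margin > 0)
  structure(list(kind = "familiarity", variant = variant, scale = scale,
                 blocks = blocks, stim_fraction = stim_fraction,
                 stim_multiplier = stim_multiplier, n_reps = n_reps,
                 present_ms = present_ms, isi_ms = isi_ms,
                 break_ms = break_ms, probe_ms = probe_ms, margin = margin,
                 rate_band = rate_band, ext_rate_range = ext_rate_range,
                 w_mean_range = w_mean_range, bounds = bounds,
                 lambda_l1 = lambda_l1, penalty_cap = penalty_cap,
                 n_trials = n_trials, dt_ms = dt_ms),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec: %s, %s/%s, plastic blocks: %s>\n", x$kind,
              x$variant, x$scale, paste(x$blocks, collapse = ", ")))
  invisible(x)
}

# per-trial randomized topology: external rate and mean initial weights
.trial_topology <- function(task, trial_seed) {
  set.seed(derive_seed(trial_seed, 101))
  ext_rate <- runif(1, task$ext_rate_range[1], task$ext_rate_range[2])
  wm <- as.list(runif(6, task$w_mean_range[1], task$w_mean_range[2]))
  names(wm) <- c("ee", "ei", "ie", "ii", "xe", "xi")
  cfg <- topology_config(task$variant, task$scale, r_ext = ext_rate,
                         w_mean = wm)
  list(config = cfg, ext_rate = ext_rate)
}

.assignment_for_task <- function(task, rules) {
  args <- stats::setNames(vector("list", 4), c("ee", "ei", "ie", "ii"))
  args[task$blocks] <- rules
  rule_assignment(ee = args$ee, ei = args$ei, ie = args$ie, ii = args$ii,
                  bounds = task$bounds)
}

#' Run one randomized trial of the stability task
#'
#' Draws the trial's external rate, initial mean weights and connectivity
#' from `trial_seed`, then simulates the plastic network for the task's
#' training duration and records the population-rate series and the
#' evaluation-window rates.
#'
#' @param assignment A [rule_assignment()] (at least one plastic block for
#'   meta-learning runs; all-static runs are valid controls).
#' @param trial_seed Integer trial seed; identical seeds give identical
#'   results.
#' @param task A [stability_task()].
#' @param record_spikes Keep the full raster (off by default in the inner
#'   loop).
#' @return An `episode_result` with element `eval_rates` holding the mean
#'   excitatory rate per evaluation window, and attribute `ext_rate`.
#' @export
run_stability_episode <- function(assignment, trial_seed, task,
                                  record_spikes = FALSE) {
  stopifnot(inherits(task, "task_spec"), task$kind == "stability")
  tr <- .trial_topology(task, trial_seed)
  net <- build_network(task$variant, tr$config,
                       seed = derive_seed(trial_seed, 102))
  t0 <- task$duration_ms * (1 - task$eval_fraction)
  starts <- seq(t0, task$duration_ms - task$eval_window_ms,
                by = task$eval_window_ms)
  ew <- cbind(starts, starts + task$eval_window_ms)
  set.seed(derive_seed(trial_seed, 103))
  res <- simulate_episode(net, assignment, input = tr$ext_rate,
                          duration_ms = task$duration_ms, dt_ms = task$dt_ms,
                          eval_windows = ew, record_spikes = record_spikes,
                          n_weight_samples = 20)
  attr(res, "ext_rate") <- tr$ext_rate
  res
}

#' Stability-task loss
#'
#' Mean over the evaluation windows of the normalized squared rate error
#' `((r_E - target) / target)^2`, plus `lambda_l1` times the L1 norm of the
#' rule amplitudes (log time constants excluded).  Diverged episodes map to
#' the fixed penalty cap so the optimizer's ranking stays well defined.
#'
#' @param result An `episode_result` from [run_stability_episode()].
#' @param task The [stability_task()].
#' @param theta Optional encoded parameter vector (for the L1 term).
#' @param space Search-space label of `theta`.
#' @return A scalar loss, >= 0.
#' @export
stability_loss <- function(result, task, theta = NULL,
                           space = "small_poly") {
  if (isTRUE(result$diverged)) return(task$penalty_cap)
  r <- result$eval_rates
  if (length(r) == 0 || anyNA(r)) return(task$penalty_cap)
  loss <- mean(((r - task$target_rate) / task$target_rate)^2)
  if (!is.null(theta))
    loss <- loss + task$lambda_l1 * .l1_amplitudes(theta, space)
  min(loss, task$penalty_cap)
}

#' Build the stimulus subsets and input schedule of a familiarity trial
#'
#' Samples disjoint familiar and novel input subsets and lays out the
#' schedule: `n_reps` familiar presentations (with inter-stimulus
#' intervals), a background-only break, then a novel probe followed by a
#' familiar probe.  Plasticity is frozen from the first probe on, so probes
#' measure the learned state.
#'
#' @param task A [familiarity_task()].
#' @param n_ext Number of input neurons.
#' @param base_rate Background input rate (Hz).
#' @param seed Integer seed (subsets and Poisson draws).
#' @param dt_ms Integration step (ms).
#' @return A list: `stimulus` (familiar / novel index sets, multiplier),
#'   `segments` (start, end, type), `input` (event schedule),
#'   `probe_windows` (2 x 2 matrix: novel then familiar), `freeze_after_ms`
#'   and `duration_ms`.
#' @export
make_familiarity_protocol <- function(task, n_ext, base_rate, seed,
                                      dt_ms = task$dt_ms) {
  stopifnot(inherits(task, "task_spec"), task$kind == "familiarity")
  n_stim <- max(1L, as.integer(round(task$stim_fraction * n_ext)))
  if (2 * n_stim > n_ext) stop("stimulus subsets do not fit in n_ext")
  set.seed(as.integer(seed))
  both <- sample.int(n_ext, 2L * n_stim)
  familiar <- sort(both[seq_len(n_stim)])
  novel <- sort(both[n_stim + seq_len(n_stim)])

  train_ms <- task$n_reps * (task$present_ms + task$isi_ms)
  t_break <- train_ms + task$break_ms
  dur <- t_break + 2 * task$probe_ms
  seg <- data.frame(start = numeric(0), end = numeric(0),
                    type = character(0), stringsAsFactors = FALSE)
  tcur <- 0
  for (k in seq_len(task$n_reps)) {
    seg <- rbind(seg, data.frame(start = tcur, end = tcur + task$present_ms,
                                 type = "familiar"))
    tcur <- tcur + task$present_ms
    if (task$isi_ms > 0) {
      seg <- rbind(seg, data.frame(start = tcur, end = tcur + task$isi_ms,
                                   type = "background"))
      tcur <- tcur + task$isi_ms
    }
  }
  seg <- rbind(seg,
               data.frame(start = tcur, end = t_break, type = "background"),
               data.frame(start = t_break, end = t_break + task$probe_ms,
                          type = "novel_probe"),
               data.frame(start = t_break + task$probe_ms, end = dur,
                          type = "familiar_probe"))

  stim_rate <- task$stim_multiplier * base_rate
  all_ids <- seq_len(n_ext)
  evs <- list()
  for (k in seq_len(nrow(seg))) {
    s <- seg[k, ]
    stim_ids <- switch(s$type, familiar = familiar,
                       familiar_probe = familiar,
                       novel_probe = novel, integer(0))
    bg_ids <- setdiff(all_ids, stim_ids)
    evs[[length(evs) + 1]] <-
      .poisson_events(bg_ids, base_rate, s$start, s$end, dt_ms)
    if (length(stim_ids) > 0)
      evs[[length(evs) + 1]] <-
        .poisson_events(stim_ids, stim_rate, s$start, s$end, dt_ms)
  }
  input <- do.call(.merge_events, evs)
  input$n_ext <- n_ext; input$duration_ms <- dur; input$dt_ms <- dt_ms
  probe_windows <- rbind(novel = c(t_break, t_break + task$probe_ms),
                         familiar = c(t_break + task$probe_ms, dur))
  list(stimulus = list(familiar = familiar, novel = novel,
                       multiplier = task$stim_multiplier,
                       base_rate = base_rate),
       segments = seg, input = input, probe_windows = probe_windows,
       freeze_after_ms = t_break, duration_ms = dur)
}

#' Run one randomized trial of the familiarity task
#'
#' @inheritParams run_stability_episode
#' @param task A [familiarity_task()].
#' @return An `episode_result` with extra elements `r_familiar` and
#'   `r_novel` (mean excitatory rates during the two probes).
#' @export
run_familiarity_episode <- function(assignment, trial_seed, task,
                                    record_spikes = FALSE) {
  stopifnot(inherits(task, "task_spec"), task$kind == "familiarity")
  tr <- .trial_topology(task, trial_seed)
  net <- build_network(task$variant, tr$config,
                       seed = derive_seed(trial_seed, 102))
  proto <- make_familiarity_protocol(task, net$n_ext, tr$ext_rate,
                                     seed = derive_seed(trial_seed, 103))
  res <- simulate_episode(net, assignment, input = proto$input,
                          duration_ms = proto$duration_ms,
                          dt_ms = task$dt_ms,
                          eval_windows = proto$probe_windows,
                          freeze_after_ms = proto$freeze_after_ms,
                          record_spikes = record_spikes,
                          n_weight_samples = 20)
  res$r_novel <- res$eval_rates[1]
  res$r_familiar <- res$eval_rates[2]
  attr(res, "ext_rate") <- tr$ext_rate
  res
}

#' Familiarity-task loss
#'
#' A hinge on the familiar-minus-novel probe response,
#' `max(0, r_novel + margin - r_familiar) / margin`, plus a plausibility
#' term penalizing mean excitatory rates outside the configured band, plus
#' L1 regularization on the rule amplitudes.  Diverged episodes map to the
#' penalty cap.
#'
#' @param result An `episode_result` from [run_familiarity_episode()] (or a
#'   list with `r_familiar`, `r_novel` and `rates`).
#' @param task The [familiarity_task()].
#' @param theta,space Optional encoded parameter vector and its space (L1
#'   term).
#' @return A scalar loss, >= 0.
#' @export
familiarity_loss <- function(result, task, theta = NULL,
                             space = "small_poly") {
  if (isTRUE(result$diverged)) return(task$penalty_cap)
  rf <- result$r_familiar; rn <- result$r_novel
  if (is.null(rf) || is.null(rn) || anyNA(c(rf, rn)))
    return(task$penalty_cap)
  loss <- max(0, rn + task$margin - rf) / task$margin
  rbar <- mean(result$rates$rate_exc)
  lo <- task$rate_band[1]; hi <- task$rate_band[2]
  loss <- loss + max(0, (lo - rbar) / lo) + max(0, (rbar - hi) / hi)
  if (!is.null(theta))
    loss <- loss + task$lambda_l1 * .l1_amplitudes(theta, space)
  min(loss, task$penalty_cap)
}

#' Evaluate one candidate parameter vector over randomized trials
#'
#' Decodes `theta` into one rule per plastic block of the task (co-active
#' blocks consume consecutive segments of the vector), runs `n_trials`
#' randomized trials with distinct derived seeds, and returns the arithmetic
#' mean of the per-trial losses.  Deterministic given `(theta, seed_base)`.
#'
#' @param theta Encoded parameter vector, length
#'   `length(task$blocks) * theta_length(space)`.
#' @param space Search-space label.
#' @param task A `task_spec`.
#' @param n_trials Number of trials (defaults to the task's setting).
#' @param seed_base Seed from which per-trial seeds are derived.
#' @param frozen_seed Frozen-layer seed (MLP space).
#' @return Mean loss (scalar) with attribute `trials`: a data frame of
#'   per-trial seeds, losses and divergence flags.
#' @export
evaluate_candidate <- function(theta, space, task, n_trials = task$n_trials,
                               seed_base, frozen_seed = 42L) {
  stopifnot(inherits(task, "task_spec"), n_trials >= 1)
  d <- theta_length(space)
  nb <- length(task$blocks)
  if (length(theta) != d * nb)
    stop(sprintf("theta must have length %d (%d blocks x %d)", d * nb, nb, d))
  rules <- lapply(seq_len(nb), function(b)
    decode_theta(theta[(b - 1) * d + seq_len(d)], space,
                 frozen_seed = frozen_seed))
  assignment <- .assignment_for_task(task, rules)
  losses <- numeric(n_trials)
  div <- logical(n_trials)
  seeds <- integer(n_trials)
  for (k in seq_len(n_trials)) {
    seeds[k] <- derive_seed(seed_base, k)
    res <- if (task$kind == "stability")
      run_stability_episode(assignment, seeds[k], task)
    else run_familiarity_episode(assignment, seeds[k], task)
    losses[k] <- if (task$kind == "stability")
      stability_loss(res, task, theta, space)
    else familiarity_loss(res, task, theta, space)
    div[k] <- res$diverged
  }
  structure(mean(losses),
            trials = data.frame(seed = seeds, loss = losses,
                                diverged = div))
}
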