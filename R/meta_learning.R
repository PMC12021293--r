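#' Meta-learn a plasticity rule with CMA-ES
#'
#' Outer optimization loop: starting from the quiescent rule, each
#' meta-iteration samples a generation of candidate parameter vectors,
#' evaluates each over randomized inner-loop network trials
#' ([evaluate_candidate()]) and updates the search distribution
#' ([cmaes_tell()]).  The same per-generation trial seeds are shared by all
#' candidates of a generation (common random numbers), so ranking noise
#' comes from the rules, not from different network draws.
#'
#' @param task A [stability_task()] or [familiarity_task()].
#' @param space Search-space label (`"small_poly"`, `"big_poly"`, `"mlp"`).
#' @param seed Master seed; the whole trajectory is a pure function of
#'   `(task, space, settings, seed)`.
#' @param max_iter Maximum number of meta-iterations.
#' @param popsize Generation size; defaults to twice the number of
#'   plasticity parameters.
#' @param n_trials Trials per candidate (defaults to the task's setting).
#' @param sigma0 Initial CMA-ES step size in encoded units.
#' @param lambda_l1 Optional override of the task's L1 weight.
#' @param stop_loss Early-stopping threshold: the run ends once the best
#'   candidate mean loss is below this value in two consecutive
#'   generations (`Inf` disables).
#' @param snapshot_iters Meta-iterations at which the covariance matrix is
#'   snapshotted (the informative window is before the loss plateaus).
#' @param frozen_seed Frozen-layer seed for the MLP space; recorded with
#'   the result since the tuned vector is meaningless without it.
#' @param theta0 Optional starting vector (defaults to the quiescent rule).
#' @param verbose Print per-iteration progress.
#'
#' @return A `meta_result`: `trajectory` (per-iteration loss statistics and
#'   mean vector), `best_rule` (rules decoded from the final mean, one per
#'   plastic block), `best_theta`, `best_candidate` (lowest evaluated mean
#'   loss anywhere in the run), covariance `snapshots`, the final
#'   `es_state`, and the run's configuration.
#' @export
run_meta_learning <- function(task, space = "small_poly", seed,
                              max_iter = 40, popsize = NULL,
                              n_trials = task$n_trials, sigma0 = 0.3,
                              lambda_l1 = NULL, stop_loss = 0.05,
                              snapshot_iters = c(10, 15, 20),
                              frozen_seed = 42L, theta0 = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(task, "task_spec"))
  if (!is.null(lambda_l1)) task$lambda_l1 <- lambda_l1
  d1 <- theta_length(space)
  nb <- length(task$blocks)
  d <- d1 * nb
  if (is.null(theta0)) {
    q <- encode_theta(init_quiescent(space, frozen_seed))
    theta0 <- rep(q, nb)
  }
  stopifnot(length(theta0) == d)
  if (is.null(popsize)) popsize <- 2L * d

  st <- cmaes_init(theta0, sigma0 = sigma0, popsize = popsize)
  traj <- list()
  snapshots <- list()
  best <- list(loss = Inf, theta = theta0, iter = 0L)
  below <- 0L

  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    X <- cmaes_ask(st, seed = derive_seed(seed, 1000L, iter))
    trial_base <- derive_seed(seed, 2000L, iter)
    losses <- numeric(ncol(X))
    for (k in seq_len(ncol(X))) {
      losses[k] <- as.numeric(
        evaluate_candidate(X[, k], space, task, n_trials = n_trials,
                           seed_base = trial_base,
                           frozen_seed = frozen_seed))
    }
    st <- cmaes_tell(st, X, losses)
    if (min(losses) < best$loss) {
      best <- list(loss = min(losses), theta = X[, which.min(losses)],
                   iter = iter)
    }
    traj[[iter]] <- c(iter = iter, best_loss = min(losses),
                      mean_loss = mean(losses),
                      median_loss = stats::median(losses),
                      sigma = st$sigma, stats::setNames(st$mean,
                                                        paste0("m", 1:d)))
    if (iter %in% snapshot_iters) snapshots[[as.character(iter)]] <- st$C
    if (verbose)
      message(sprintf("iter %3d  best %.4f  mean %.4f  sigma %.3f", iter,
                      min(losses), mean(losses), st$sigma))
    below <- if (min(losses) < stop_loss) below + 1L else 0L
    if (below >= 2L) break
  }

  trajectory <- as.data.frame(do.call(rbind, traj))
  best_theta <- st$mean
  best_rule <- lapply(seq_len(nb), function(b)
    decode_theta(best_theta[(b - 1) * d1 + seq_len(d1)], space,
                 frozen_seed = frozen_seed))
  names(best_rule) <- task$blocks
  structure(list(trajectory = trajectory, best_rule = best_rule,
                 best_theta = best_theta, best_candidate = best,
                 snapshots = snapshots, es_state = st, task = task,
                 space = space, seed = seed, n_trials = n_trials,
                 frozen_seed = frozen_seed),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf(
    "<meta_result: %s space on %s task, %d meta-iterations>\n", x$space,
    x$task$kind, n))
  if (n > 0)
    cat(sprintf("  final best candidate loss %.4f (mean %.4f)\n",
                x$trajectory$best_loss[n], x$trajectory$mean_loss[n]))
  invisible(x)
}
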