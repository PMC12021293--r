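#' Pre/post pairing-protocol curve of a plasticity rule
#'
#' The classic diagnostic for spike-timing dependence: for each delay
#' `dt` (post minus pre, ms) an isolated pre/post spike pair is simulated
#' from zeroed traces and the total weight change (sum of both
#' spike-triggered updates) is reported.  For the separable-polynomial and
#' MLP spaces the protocol does not constrain the membrane-dependent
#' variables, so their clamped values are explicit metadata of the curve.
#' A pair-train mode (`n_pairs > 1`) repeats the pair at a fixed pairing
#' interval.
#'
#' @param rule A `plasticity_rule`.
#' @param dt_grid Delays (ms); the default grid is symmetric around 0.
#' @param w0 Clamped initial weight (mid-range of the default bounds).
#' @param V_avg,C_E,C_I Clamped auxiliary variables (`V_avg` defaults to a
#'   typical resting potential).
#' @param n_pairs Number of pre/post pairs per delay.
#' @param pair_interval_ms Interval between successive pairs.
#' @param dt_ms Integration step.
#' @return A `pre_post_curve`: data frame with `dt_ms` and `dw`, protocol
#'   metadata in attributes.
#' @export
#' @examples
#' r <- small_poly_rule(gamma = 1, tau_pre = 10)
#' cv <- pre_post_curve(r, dt_grid = c(-10, 10))
#' cv$dw # depression side 0, potentiation side exp(-1)
pre_post_curve <- function(rule, dt_grid = seq(-50, 50, by = 2), w0 = 5,
                           V_avg = -60, C_E = 0, C_I = 0, n_pairs = 1,
                           pair_interval_ms = 100, dt_ms = 0.1) {
  stopifnot(inherits(rule, "plasticity_rule"), n_pairs >= 1)
  clamps <- c(V_avg = V_avg, C_E = C_E, C_I = C_I)
  dw <- vapply(dt_grid, function(dtv) {
    off <- max(0, -dtv) + dt_ms
    pre <- off + (seq_len(n_pairs) - 1) * pair_interval_ms
    post <- pre + dtv
    dur <- max(pre, post) + 10 * dt_ms
    res <- apply_rule_to_spike_train(rule, pre, post, duration_ms = dur,
                                     dt_ms = dt_ms, w0 = w0,
                                     bounds = c(-Inf, Inf), clamps = clamps)
    res$w_final - w0
  }, numeric(1))
  structure(data.frame(dt_ms = dt_grid, dw = dw),
            class = c("pre_post_curve", "data.frame"),
            protocol = list(w0 = w0, clamps = clamps, n_pairs = n_pairs,
                            pair_interval_ms = pair_interval_ms,
                            dt_ms = dt_ms),
            space = rule_space(rule))
}

#' @export
print.pre_post_curve <- function(x, ...) {
  cat(sprintf("<pre_post_curve: %s rule, %d delays in [%g, %g] ms>\n",
              attr(x, "space"), nrow(x), min(x$dt_ms), max(x$dt_ms)))
  invisible(x)
}

#' @export
plot.pre_post_curve <- function(x, ...) {
  graphics::plot(x$dt_ms, x$dw, type = "l",
                 xlab = expression(Delta * t == t[post] - t[pre] ~ "(ms)"),
                 ylab = expression(Delta * w), ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey50")
  invisible(x)
}

# coefficient of variation of inter-spike intervals, averaged over neurons
# with at least min_isi intervals; ~1 for Poisson firing, ~0 for clocks
.isi_cv <- function(raster, min_isi = 3) {
  if (nrow(raster) == 0) return(NA_real_)
  cvs <- vapply(split(raster$time_ms, raster$id), function(tt) {
    if (length(tt) < min_isi + 1) return(NA_real_)
    isi <- diff(sort(tt))
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  if (all(is.na(cvs))) NA_real_ else mean(cvs, na.rm = TRUE)
}

# Sarle's bimodality coefficient from population moments; 5/9 for a
# uniform distribution, larger for bimodal ones
.bimodality <- function(w) {
  n <- length(w)
  if (n < 4 || stats::sd(w) == 0) return(NA_real_)
  m <- mean(w)
  m2 <- mean((w - m)^2)
  g1 <- mean((w - m)^3) / m2^1.5
  g2 <- mean((w - m)^4) / m2^2
  (g1^2 + 1) / g2
}

#' Summary statistics of one simulated episode
#'
#' Per-population mean firing rate and inter-spike-interval coefficient of
#' variation, fraction of silent neurons, and per-plastic-block weight
#' statistics: mean, fraction at the lower bound, fraction saturated at the
#' upper bound, and Sarle's bimodality coefficient of the weight
#' distribution.  All metrics are invariant under relabeling of neurons.
#'
#' @param result An `episode_result` simulated with `record_spikes = TRUE`.
#' @param bounds Weight bounds used to score saturation.
#' @param tol Relative tolerance for counting a weight as at-bound.
#' @return A list of class `episode_summary`.
#' @export
episode_summary <- function(result, bounds = c(0, 10), tol = 1e-6) {
  stopifnot(inherits(result, "episode_result"))
  if (is.null(result$raster_exc))
    stop("episode was simulated without spike recording")
  dur_s <- result$duration_ms / 1000
  mean_rate <- function(r) nrow(r) / (attr(r, "n_neurons") * dur_s)
  frac_silent <- function(r)
    1 - length(unique(r$id)) / attr(r, "n_neurons")
  wsum <- lapply(result$w_final, function(w) {
    span <- max(bounds[2] - bounds[1], 1e-12)
    c(mean = mean(w),
      frac_lo = mean(w <= bounds[1] + tol * span),
      frac_saturated = mean(w >= bounds[2] - tol * span),
      bimodality = .bimodality(w))
  })
  structure(list(
    rate_hz = c(exc = mean_rate(result$raster_exc),
                inh = mean_rate(result$raster_inh)),
    isi_cv = c(exc = .isi_cv(result$raster_exc),
               inh = .isi_cv(result$raster_inh)),
    fraction_silent = c(exc = frac_silent(result$raster_exc),
                        inh = frac_silent(result$raster_inh)),
    weights = do.call(rbind, wsum),
    diverged = result$diverged), class = "episode_summary")
}

#' @export
print.episode_summary <- function(x, ...) {
  cat("<episode_summary>\n")
  cat(sprintf("  rates:  E %.2f Hz, I %.2f Hz\n", x$rate_hz[1],
              x$rate_hz[2]))
  cat(sprintf("  ISI CV: E %.2f, I %.2f\n", x$isi_cv[1], x$isi_cv[2]))
  cat(sprintf("  silent: E %.1f%%, I %.1f%%\n",
              100 * x$fraction_silent[1], 100 * x$fraction_silent[2]))
  invisible(x)
}
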