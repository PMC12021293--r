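#' Mean-field fixed-point rate predicted by a pair-based rule
#'
#' For a single synapse type plastic in isolation under the pair-based
#' polynomial rule, setting the expected weight drift to zero under
#' independent Poisson firing yields a closed-form steady-state population
#' rate.  With the Hebbian combination `H = kappa * tau_post + gamma *
#' tau_pre` (time constants in seconds):
#'
#' * I-to-E: `r_exc* = -alpha * r_inh / (beta + H * r_inh)`, stable when
#'   `alpha < 0` and the denominator is positive;
#' * E-to-I: `r_inh* = -alpha * r_exc / (beta + H * r_exc)`;
#' * E-to-E and I-to-I: `r_inh* = -(alpha + beta) / H`.
#'
#' Rates are only reported when the relevant denominator is nonzero.
#'
#' @param synapse_type One of `"ie"`, `"ee"`, `"ei"`, `"ii"`.
#' @param rule A [small_poly_rule()] (time constants in ms; converted to
#'   seconds internally).
#' @param counterpart_rate_hz Steady rate of the presynaptic population's
#'   counterpart (required for `"ie"` and `"ei"`, where the fixed point
#'   depends on it).
#' @return A `meanfield_prediction`: the predicted rate (`NA` when
#'   undefined), the Hebbian combination `H` (in seconds), and stability
#'   flags.
#' @export
#' @examples
#' r <- small_poly_rule(alpha = -1, kappa = 0.1 / 0.01, tau_post = 10)
#' meanfield_rate("ie", r, counterpart_rate_hz = 20) # 10 Hz for any r_inh
meanfield_rate <- function(synapse_type = c("ie", "ee", "ei", "ii"), rule,
                           counterpart_rate_hz = NULL) {
  synapse_type <- match.arg(synapse_type)
  stopifnot(inherits(rule, "small_poly_rule"))
  a <- rule$alpha; b <- rule$beta
  H <- rule$kappa * rule$tau_post / 1000 + rule$gamma * rule$tau_pre / 1000
  flags <- c(alpha_negative = a < 0, denominator_positive = NA)
  rate <- NA_real_
  if (synapse_type %in% c("ie", "ei")) {
    if (is.null(counterpart_rate_hz))
      stop(sprintf("synapse type %s requires counterpart_rate_hz",
                   synapse_type))
    rc <- counterpart_rate_hz
    den <- b + H * rc
    flags["denominator_positive"] <- den > 0
    if (den != 0) rate <- -a * rc / den
  } else {
    flags["denominator_positive"] <- H > 0
    if (H != 0) rate <- -(a + b) / H
  }
  structure(list(synapse_type = synapse_type, rate_hz = rate, H = H,
                 alpha = a, beta = b,
                 counterpart_rate_hz = counterpart_rate_hz,
                 stable = isTRUE(flags[1]) && isTRUE(flags[2]),
                 flags = flags),
            class = "meanfield_prediction")
}

#' @export
print.meanfield_prediction <- function(x, ...) {
  cat(sprintf("<meanfield_prediction: %s>\n", x$synapse_type))
  cat(sprintf("  fixed-point rate: %s Hz\n",
              if (is.na(x$rate_hz)) "undefined" else
                sprintf("%.3f", x$rate_hz)))
  cat(sprintf("  H = kappa*tau_post + gamma*tau_pre = %.4g s\n", x$H))
  cat(sprintf("  stable: %s (alpha<0: %s, denominator>0: %s)\n", x$stable,
              x$flags[1], x$flags[2]))
  invisible(x)
}

#' Complete a pair-based rule so its mean-field fixed point hits a target
#'
#' Inverts the fixed-point expression of [meanfield_rate()] for exactly one
#' free amplitude (`alpha`, `beta`, `gamma` or `kappa`), keeping the others
#' at the values given.  The returned rule satisfies
#' `meanfield_rate(...)$rate_hz == target_rate` exactly; an error is raised
#' when the inversion has no solution compatible with the stability
#' conditions of the synapse type.
#'
#' @param synapse_type One of `"ie"`, `"ee"`, `"ei"`, `"ii"`.
#' @param target_rate Target rate (Hz), > 0.
#' @param free Which amplitude to solve for.
#' @param rule A [small_poly_rule()] providing the fixed parameters (the
#'   free one is ignored).
#' @param counterpart_rate_hz Counterpart population rate (for `"ie"` /
#'   `"ei"`).
#' @return The completed `small_poly_rule`.
#' @export
#' @examples
#' solve_for_target("ee", 10, free = "kappa",
#'                  rule = small_poly_rule(alpha = -0.05, beta = -0.05,
#'                                         tau_post = 20))
solve_for_target <- function(synapse_type = c("ie", "ee", "ei", "ii"),
                             target_rate, free = c("kappa", "gamma",
                                                   "alpha", "beta"),
                             rule = small_poly_rule(),
                             counterpart_rate_hz = NULL) {
  synapse_type <- match.arg(synapse_type)
  free <- match.arg(free)
  stopifnot(target_rate > 0)
  a <- rule$alpha; b <- rule$beta
  g <- rule$gamma; k <- rule$kappa
  tp <- rule$tau_pre / 1000; tq <- rule$tau_post / 1000
  if (synapse_type %in% c("ie", "ei")) {
    if (is.null(counterpart_rate_hz) || counterpart_rate_hz <= 0)
      stop("a positive counterpart_rate_hz is required")
    rc <- counterpart_rate_hz
    # -a * rc = target * (b + H * rc)
    if (free == "alpha") {
      a <- -target_rate * (b + (k * tq + g * tp) * rc) / rc
    } else if (free == "beta") {
      b <- -a * rc / target_rate - (k * tq + g * tp) * rc
    } else {
      H <- (-a * rc / target_rate - b) / rc
      if (free == "kappa") k <- (H - g * tp) / tq else g <- (H - k * tq) / tp
    }
  } else {
    # target = -(a + b) / H
    if (free == "alpha") {
      a <- -target_rate * (k * tq + g * tp) - b
    } else if (free == "beta") {
      b <- -target_rate * (k * tq + g * tp) - a
    } else {
      H <- -(a + b) / target_rate
      if (free == "kappa") k <- (H - g * tp) / tq else g <- (H - k * tq) / tp
    }
  }
  out <- small_poly_rule(a, b, g, k, rule$tau_pre, rule$tau_post)
  pred <- meanfield_rate(synapse_type, out, counterpart_rate_hz)
  if (!is.finite(pred$rate_hz) ||
      abs(pred$rate_hz - target_rate) > 1e-8 * max(1, target_rate))
    stop("no solution: the requested fixed point is unreachable with the ",
         "fixed parameters")
  if (synapse_type == "ie" && !pred$stable)
    stop("solution violates the stability conditions (alpha < 0 and ",
         "positive denominator) for I-to-E plasticity")
  out
}
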