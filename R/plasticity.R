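#' Pair-based polynomial plasticity rule (six parameters)
#'
#' First-order spike-timing-dependent rule.  A presynaptic spike changes the
#' weight by `alpha + kappa * x_post`; a postsynaptic spike by
#' `beta + gamma * x_pre`, where `x_pre` / `x_post` are exponential traces of
#' the pre- and postsynaptic spike trains with learnable time constants
#' `tau_pre` / `tau_post`.  `alpha` and `beta` are the non-Hebbian (single
#' spike) amplitudes; `gamma` and `kappa` are the Hebbian (pair) amplitudes.
#'
#' @param alpha,beta,gamma,kappa Weight-change amplitudes (unitless).
#' @param tau_pre,tau_post Trace time constants (ms), must be positive.  When
#'   the rule is optimized, their natural logarithms are the encoded
#'   parameters so positivity is automatic.
#' @return An object of classes `small_poly_rule`, `plasticity_rule`.
#' @export
#' @examples
#' r <- small_poly_rule(alpha = -0.01, kappa = 0.1)
#' encode_theta(r)
small_poly_rule <- function(alpha = 0, beta = 0, gamma = 0, kappa = 0,
                            tau_pre = 10, tau_post = 10) {
  if (tau_pre <= 0 || tau_post <= 0) stop("time constants must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 tau_pre = tau_pre, tau_post = tau_post),
            class = c("small_poly_rule", "plasticity_rule"))
}

#' Separable polynomial plasticity rule (21 parameters)
#'
#' Spike-triggered rule whose pre- and post-factors are products of
#' one-variable polynomial factors in: the weight (up to quadratic), the
#' low-passed membrane potential `<V>` (100 ms), the codependent excitatory
#' and inhibitory currents `C_E` (10 ms) and `C_I` (100 ms), and fixed
#' 10 ms / 100 ms spike traces of the pre- and postsynaptic neurons (the
#' postsynaptic long-trace factor includes a cubic term).  Amplitudes
#' `theta[1..10]` gate pre-spike updates and `theta[11..21]` post-spike
#' updates; each synaptic variable appears in exactly one factor
#' (separability).
#'
#' @param theta Numeric vector of 21 amplitudes (unitless).
#' @return An object of classes `big_poly_rule`, `plasticity_rule`.
#' @export
big_poly_rule <- function(theta = numeric(21)) {
  if (length(theta) != 21) stop("theta must have length 21")
  structure(list(theta = as.numeric(theta)),
            class = c("big_poly_rule", "plasticity_rule"))
}

#' Partially frozen multilayer-perceptron plasticity rule (11 parameters)
#'
#' Spike-triggered rule computed by two feedforward networks (one for
#' pre-spike updates, one for post-spike updates) over six synaptic
#' variables.  Hidden layers (6 -> 50 -> 4, sigmoid units) are drawn once
#' from `U(-1/sqrt(n_inp), 1/sqrt(n_inp))` under `frozen_seed` and shared by
#' both networks and by all candidates of an optimization; only the linear
#' output layer (4 weights + 1 bias per network) and one shared learning
#' rate are tunable.  The pre-network reads
#' `(x_pre_long, x_post_short, w, <V>, C_E, C_I)` and the post-network
#' `(x_pre_short, x_post_long, w, <V>, C_E, C_I)`.
#'
#' @param w_pre,b_pre Output weights (length 4) and bias of the pre-spike
#'   network.
#' @param w_post,b_post Same for the post-spike network.
#' @param learning_rate Shared multiplicative learning rate.
#' @param frozen_seed Seed of the frozen hidden layers; part of the rule's
#'   identity (a tuned parameter vector is meaningless without it).
#' @return An object of classes `mlp_rule`, `plasticity_rule`.
#' @export
mlp_rule <- function(w_pre = numeric(4), b_pre = 0, w_post = numeric(4),
                     b_post = 0, learning_rate = 0, frozen_seed = 42L) {
  if (length(w_pre) != 4 || length(w_post) != 4)
    stop("w_pre and w_post must have length 4")
  structure(list(w_pre = as.numeric(w_pre), b_pre = b_pre,
                 w_post = as.numeric(w_post), b_post = b_post,
                 learning_rate = learning_rate,
                 frozen_seed = as.integer(frozen_seed)),
            class = c("mlp_rule", "plasticity_rule"))
}

#' @export
print.plasticity_rule <- function(x, ...) {
  sp <- rule_space(x)
  th <- encode_theta(x)
  cat(sprintf("<plasticity_rule: %s, %d parameters>\n", sp, length(th)))
  cat("  theta:", paste(signif(th, 4), collapse = " "), "\n")
  invisible(x)
}

#' Search-space label of a rule
#' @param rule A `plasticity_rule`.
#' @return One of `"small_poly"`, `"big_poly"`, `"mlp"`.
#' @export
rule_space <- function(rule) {
  if (inherits(rule, "small_poly_rule")) return("small_poly")
  if (inherits(rule, "big_poly_rule")) return("big_poly")
  if (inherits(rule, "mlp_rule")) return("mlp")
  stop("not a plasticity rule")
}

#' Frozen hidden layers of the MLP rule
#'
#' Materializes the fixed hidden weights for a given seed: layer 1 is 50 x 6,
#' layer 2 is 4 x 50, entries `U(-1/sqrt(n_inp), 1/sqrt(n_inp))` with
#' `n_inp` the fan-in of the layer.  Hidden units carry no bias.  The draw
#' does not disturb the caller's RNG stream.
#'
#' @param frozen_seed Integer seed.
#' @return List with matrices `W1` (50 x 6) and `W2` (4 x 50).
#' @export
mlp_frozen_weights <- function(frozen_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(frozen_seed))
  b1 <- 1 / sqrt(6)
  W1 <- matrix(runif(50 * 6, -b1, b1), nrow = 50, ncol = 6)
  b2 <- 1 / sqrt(50)
  W2 <- matrix(runif(4 * 50, -b2, b2), nrow = 4, ncol = 50)
  list(W1 = W1, W2 = W2)
}

# ---------------------------------------------------------------------------
# parameter-vector codecs

#' Encode a plasticity rule as a flat parameter vector
#'
#' The encoded vector is the optimizer's search coordinate: 6 entries for the
#' pair-based polynomial (`alpha, beta, gamma, kappa, log(tau_pre),
#' log(tau_post)`; time constants are optimized on the natural-log scale so
#' any real vector decodes to positive time constants), 21 for the separable
#' polynomial, 11 for the MLP rule (`w_pre, b_pre, w_post, b_post,
#' learning_rate`).
#'
#' @param rule A `plasticity_rule`.
#' @return Numeric vector of length 6, 21 or 11.
#' @export
encode_theta <- function(rule) {
  UseMethod("encode_theta")
}

#' @export
encode_theta.small_poly_rule <- function(rule) {
  c(rule$alpha, rule$beta, rule$gamma, rule$kappa,
    log(rule$tau_pre), log(rule$tau_post))
}

#' @export
encode_theta.big_poly_rule <- function(rule) rule$theta

#' @export
encode_theta.mlp_rule <- function(rule) {
  c(rule$w_pre, rule$b_pre, rule$w_post, rule$b_post, rule$learning_rate)
}

#' Decode a flat parameter vector into a plasticity rule
#'
#' Inverse of [encode_theta()]; `decode_theta(encode_theta(r), rule_space(r))`
#' reproduces `r` exactly.
#'
#' @param theta Numeric vector (length 6 / 21 / 11 according to `space`).
#' @param space `"small_poly"`, `"big_poly"` or `"mlp"`.
#' @param frozen_seed Frozen-layer seed (MLP space only).
#' @return A `plasticity_rule`.
#' @export
decode_theta <- function(theta, space = c("small_poly", "big_poly", "mlp"),
                         frozen_seed = 42L) {
  space <- match.arg(space)
  n <- theta_length(space)
  if (length(theta) != n)
    stop(sprintf("theta must have length %d for the %s space", n, space))
  switch(space,
    small_poly = small_poly_rule(theta[1], theta[2], theta[3], theta[4],
                                 exp(theta[5]), exp(theta[6])),
    big_poly = big_poly_rule(theta),
    mlp = mlp_rule(theta[1:4], theta[5], theta[6:9], theta[10], theta[11],
                   frozen_seed = frozen_seed))
}

#' Dimension of an encoded parameter vector
#' @param space Search-space label.
#' @return 6, 21 or 11.
#' @export
theta_length <- function(space = c("small_poly", "big_poly", "mlp")) {
  switch(match.arg(space), small_poly = 6L, big_poly = 21L, mlp = 11L)
}

#' Quiescent initial rule for a search space
#'
#' All amplitudes zero so that no weight changes occur on any episode; the
#' recommended starting point of the outer optimization.  Trace time
#' constants default to 10 ms in the pair-based space.
#'
#' @param space Search-space label.
#' @param frozen_seed Frozen-layer seed (MLP space).
#' @return A `plasticity_rule` whose every update is exactly zero.
#' @export
init_quiescent <- function(space = c("small_poly", "big_poly", "mlp"),
                           frozen_seed = 42L) {
  space <- match.arg(space)
  switch(space,
    small_poly = small_poly_rule(),
    big_poly = big_poly_rule(),
    mlp = mlp_rule(frozen_seed = frozen_seed))
}

# ---------------------------------------------------------------------------
# single-event weight increments (reference arithmetic; the episode
# integrator runs the same expressions in compiled code)

#' Weight increment of the pair-based polynomial rule at one spike event
#'
#' @param rule A [small_poly_rule()].
#' @param event `"pre"` or `"post"`.
#' @param x_pre,x_post Trace values sampled at the event, before the spiking
#'   neuron's own +1 increment.
#' @return The weight change (unitless).
#' @export
small_poly_delta <- function(rule, event = c("pre", "post"), x_pre = 0,
                             x_post = 0) {
  event <- match.arg(event)
  if (event == "pre") rule$alpha + rule$kappa * x_post
  else rule$beta + rule$gamma * x_pre
}

#' Weight increment of the separable polynomial rule at one spike event
#'
#' @param rule A [big_poly_rule()].
#' @param event `"pre"` or `"post"`.
#' @param x_short_pre,x_long_pre,x_short_post,x_long_post Fixed 10 ms /
#'   100 ms traces of the pre- and postsynaptic neurons at the event.
#' @param w Current synaptic weight.
#' @param V_avg Low-passed postsynaptic membrane potential (mV).
#' @param C_E,C_I Codependent excitatory / inhibitory current terms.
#' @return The weight change (unitless).
#' @export
big_poly_delta <- function(rule, event = c("pre", "post"), x_short_pre = 0,
                           x_long_pre = 0, x_short_post = 0, x_long_post = 0,
                           w = 0, V_avg = 0, C_E = 0, C_I = 0) {
  event <- match.arg(event)
  th <- rule$theta
  if (event == "pre") {
    th[1] * (1 + th[2] + th[3] * w + th[4] * w^2) * (1 + th[5] * V_avg) *
      (1 + th[6] * C_E + th[7] * C_E^2) * (1 + th[8] * C_I) *
      (1 + th[9] * x_long_pre) * (1 + th[10] * x_short_post)
  } else {
    th[11] * (1 + th[12] + th[13] * w + th[14] * w^2) * (1 + th[15] * V_avg) *
      (1 + th[16] * C_E + th[17] * C_E^2) * (1 + th[18] * C_I) *
      (1 + th[19] * x_short_pre) *
      (1 + th[20] * x_long_post + th[21] * x_long_post^3)
  }
}

#' Weight increment of the MLP rule at one spike event
#'
#' @param rule An [mlp_rule()].
#' @param event `"pre"` or `"post"`.
#' @param inputs Numeric vector of the six synaptic variables in network
#'   order: pre trace (long for pre events, short for post events), post
#'   trace (short for pre events, long for post events), `w`, `<V>`, `C_E`,
#'   `C_I`.
#' @param frozen Optional precomputed [mlp_frozen_weights()] (avoids
#'   re-materializing them in tight loops).
#' @return The weight change (unitless).
#' @export
mlp_delta <- function(rule, event = c("pre", "post"), inputs,
                      frozen = NULL) {
  event <- match.arg(event)
  stopifnot(length(inputs) == 6)
  if (is.null(frozen)) frozen <- mlp_frozen_weights(rule$frozen_seed)
  h1 <- 1 / (1 + exp(-(frozen$W1 %*% inputs)))
  h2 <- 1 / (1 + exp(-(frozen$W2 %*% h1)))
  if (event == "pre")
    rule$learning_rate * (sum(rule$w_pre * h2) + rule$b_pre)
  else
    rule$learning_rate * (sum(rule$w_post * h2) + rule$b_post)
}

# ---------------------------------------------------------------------------

#' Clip weights to block bounds
#'
#' Hard clipping to `[lo, hi]`, applied by the integrator after every single
#' update; idempotent.
#'
#' @param w Numeric weights.
#' @param bounds Length-2 numeric `c(lo, hi)` with `0 <= lo <= hi`.
#' @return Clipped weights.
#' @export
#' @examples
#' apply_bounds(c(-0.3, 5, 12), c(0, 10))
apply_bounds <- function(w, bounds = c(0, 10)) {
  if (length(bounds) != 2 || bounds[1] > bounds[2])
    stop("bounds must be c(lo, hi) with lo <= hi")
  if (bounds[1] < 0) stop("lower bound must be >= 0")
  pmin(bounds[2], pmax(bounds[1], w))
}

#' Assign plasticity rules to connection blocks
#'
#' Maps each recurrent synapse block to a rule instance or leaves it static.
#' External-input synapses are always static.
#'
#' @param ee,ei,ie,ii A `plasticity_rule` or `NULL` (static).
#' @param bounds Weight bounds applied to every plastic block, default
#'   `c(0, 10)`; may also be a named list of per-block bounds.
#' @return An object of class `rule_assignment`.
#' @export
#' @examples
#' rule_assignment(ie = small_poly_rule(alpha = -0.01, kappa = 0.1))
rule_assignment <- function(ee = NULL, ei = NULL, ie = NULL, ii = NULL,
                            bounds = c(0, 10)) {
  rules <- list(ee = ee, ei = ei, ie = ie, ii = ii)
  for (nm in names(rules))
    if (!is.null(rules[[nm]]) && !inherits(rules[[nm]], "plasticity_rule"))
      stop(sprintf("%s must be a plasticity_rule or NULL", nm))
  if (!is.list(bounds)) {
    apply_bounds(0, bounds) # validates
    bounds <- list(ee = bounds, ei = bounds, ie = bounds, ii = bounds)
  }
  structure(list(rules = rules, bounds = bounds), class = "rule_assignment")
}

#' @export
print.rule_assignment <- function(x, ...) {
  cat("<rule_assignment>\n")
  for (nm in names(x$rules)) {
    r <- x$rules[[nm]]
    cat(sprintf("  %s: %s\n", nm, if (is.null(r)) "static" else rule_space(r)))
  }
  invisible(x)
}

#' Plastic blocks of an assignment
#' @param assignment A [rule_assignment()].
#' @return Character vector of block names with a rule attached.
#' @export
plastic_blocks <- function(assignment) {
  names(Filter(Negate(is.null), assignment$rules))
}

# internal: cpp block spec for one network block + optional rule
.block_for_cpp <- function(block, rule, bounds) {
  spec <- list(pre = block$pre, post = block$post, w = block$w,
               npre = block$npre, npost = block$npost,
               pre_pop = block$pre_pop, post_pop = block$post_pop,
               space = 0L, theta = numeric(0), lo = 0, hi = 10,
               tau_pre = 10, tau_post = 10, W1 = NULL, W2 = NULL)
  if (is.null(rule)) return(spec)
  spec$lo <- bounds[1]; spec$hi <- bounds[2]
  sp <- rule_space(rule)
  if (sp == "small_poly") {
    spec$space <- 1L
    spec$theta <- c(rule$alpha, rule$beta, rule$gamma, rule$kappa)
    spec$tau_pre <- rule$tau_pre; spec$tau_post <- rule$tau_post
  } else if (sp == "big_poly") {
    spec$space <- 2L
    spec$theta <- rule$theta
  } else {
    spec$space <- 3L
    spec$theta <- encode_theta(rule)
    fz <- mlp_frozen_weights(rule$frozen_seed)
    spec$W1 <- fz$W1; spec$W2 <- fz$W2
  }
  spec
}
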