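#' Initialize a CMA-ES search state
#'
#' Standard (mu/mu_w, lambda) Covariance Matrix Adaptation Evolution
#' Strategy with rank-one and rank-mu covariance updates and cumulative
#' step-size adaptation.  The state holds the current best guess (the
#' distribution mean), the covariance matrix, the global step size and the
#' two evolution paths.
#'
#' @param mean Initial mean vector (the starting rule's encoded
#'   parameters).
#' @param sigma0 Initial step size in encoded units (0.3 by default).
#' @param popsize Generation size `n`; by convention twice the number of
#'   parameters.
#' @return An object of class `cmaes_state`.
#' @export
#' @examples
#' st <- cmaes_init(numeric(6))
#' st$popsize
cmaes_init <- function(mean, sigma0 = 0.3, popsize = 2 * length(mean)) {
  d <- length(mean)
  stopifnot(d >= 1, sigma0 > 0, popsize >= 2)
  mu <- floor(popsize / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cs <- (mueff + 2) / (d + mueff + 5)
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))
  structure(list(dim = d, mean = as.numeric(mean), sigma = sigma0,
                 C = diag(d), pc = numeric(d), ps = numeric(d), gen = 0L,
                 popsize = as.integer(popsize), mu = mu, weights = w,
                 mueff = mueff, cs = cs, damps = damps, cc = cc, c1 = c1,
                 cmu = cmu, chiN = chiN),
            class = "cmaes_state")
}

#' @export
print.cmaes_state <- function(x, ...) {
  cat(sprintf(
    "<cmaes_state: dim %d, generation %d, sigma %.4g, popsize %d>\n",
    x$dim, x$gen, x$sigma, x$popsize))
  invisible(x)
}

# eigendecomposition with PSD repair (eigenvalue floor); warns when a
# repair was needed
.cmaes_eig <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  floor_ev <- max(e$values) * 1e-14
  if (any(e$values < 0))
    warning("covariance matrix repaired: negative eigenvalues floored")
  e$values <- pmax(e$values, floor_ev)
  e
}

#' Sample a generation of candidate parameter vectors
#'
#' Draws `popsize` i.i.d. candidates from
#' `N(mean, sigma^2 * C)`.
#'
#' @param state A `cmaes_state`.
#' @param seed Optional seed for the draw.
#' @return A `dim x popsize` matrix, one candidate per column.
#' @export
cmaes_ask <- function(state, seed = NULL) {
  stopifnot(inherits(state, "cmaes_state"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- state$dim
  e <- .cmaes_eig(state$C)
  Z <- matrix(stats::rnorm(d * state$popsize), d, state$popsize)
  X <- state$mean +
    state$sigma * (e$vectors %*% (sqrt(e$values) * Z))
  X
}

#' Update the CMA-ES state from evaluated candidates
#'
#' Rank-based weighted-recombination mean update, rank-one plus rank-mu
#' covariance update and cumulative step-size adaptation; lower loss is
#' better.  If every candidate has the identical loss there is no ranking
#' information, so the generation counter advances with the mean unchanged.
#'
#' @param state A `cmaes_state`.
#' @param candidates The matrix returned by [cmaes_ask()] (or any
#'   `dim x popsize` matrix).
#' @param losses Numeric vector of finite losses, one per column.
#' @return The updated `cmaes_state`.
#' @export
cmaes_tell <- function(state, candidates, losses) {
  stopifnot(inherits(state, "cmaes_state"),
            ncol(candidates) == state$popsize,
            length(losses) == state$popsize, all(is.finite(losses)))
  state$gen <- state$gen + 1L
  if (diff(range(losses)) == 0) return(state)
  d <- state$dim
  ord <- order(losses)
  sel <- candidates[, ord[seq_len(state$mu)], drop = FALSE]
  Y <- (sel - state$mean) / state$sigma
  yw <- as.numeric(Y %*% state$weights)
  state$mean <- state$mean + state$sigma * yw

  e <- .cmaes_eig(state$C)
  Cinvsqrt <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  state$ps <- (1 - state$cs) * state$ps +
    sqrt(state$cs * (2 - state$cs) * state$mueff) *
    as.numeric(Cinvsqrt %*% yw)
  hsig <- sqrt(sum(state$ps^2)) /
    sqrt(1 - (1 - state$cs)^(2 * state$gen)) / state$chiN <
    1.4 + 2 / (d + 1)
  state$pc <- (1 - state$cc) * state$pc +
    (if (hsig) sqrt(state$cc * (2 - state$cc) * state$mueff) else 0) * yw
  rank_mu <- Y %*% (state$weights * t(Y))
  state$C <- (1 - state$c1 - state$cmu) * state$C +
    state$c1 * (tcrossprod(state$pc) +
                  (if (hsig) 0 else state$cc * (2 - state$cc)) * state$C) +
    state$cmu * rank_mu
  state$C <- (state$C + t(state$C)) / 2
  state$sigma <- state$sigma *
    exp(state$cs / state$damps * (sqrt(sum(state$ps^2)) / state$chiN - 1))
  state
}

#' Correlation form of the search covariance matrix
#'
#' Normalizes the covariance to unit diagonal; the correlation matrix is
#' what reveals interdependencies between plasticity parameters (for
#' example, the anti-correlation between the two non-Hebbian amplitudes of
#' successful homeostatic rules).  Components with zero variance are masked
#' with `NA`.
#'
#' @param state A `cmaes_state`, or a covariance matrix.
#' @return A symmetric matrix with unit diagonal, entries in `[-1, 1]` (or
#'   `NA` for masked components).
#' @export
correlation_matrix <- function(state) {
  C <- if (inherits(state, "cmaes_state")) state$C else as.matrix(state)
  dg <- diag(C)
  bad <- dg <= 0
  s <- sqrt(ifelse(bad, NA_real_, dg))
  R <- C / outer(s, s)
  diag(R) <- ifelse(bad, NA_real_, 1)
  R
}
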