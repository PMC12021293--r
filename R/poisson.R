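#' Homogeneous Poisson spike trains
#'
#' Generates independent per-bin Bernoulli spike trains (probability
#' `rate_hz * dt_ms / 1000` per bin), the discrete-time approximation of a
#' homogeneous Poisson process.  Events are stamped at the end of the bin in
#' which they occur.
#'
#' @param n_neurons Number of independent source neurons.
#' @param rate_hz Firing rate (Hz), identical across neurons.
#' @param duration_ms Train duration (ms).
#' @param dt_ms Bin width (ms); must satisfy `rate_hz * dt_ms / 1000 < 1`.
#' @param seed Optional integer seed.
#'
#' @return A `spike_raster`: data frame with columns `id` and `time_ms` plus
#'   attributes `n_neurons` and `duration_ms`.
#' @export
#' @examples
#' r <- poisson_spikes(100, 7, 1000, seed = 1)
#' nrow(r) / (100 * 1) # empirical rate, ~7 Hz
poisson_spikes <- function(n_neurons, rate_hz, duration_ms, dt_ms = 0.1,
                           seed = NULL) {
  stopifnot(n_neurons >= 1, rate_hz >= 0, duration_ms > 0, dt_ms > 0)
  p <- rate_hz * dt_ms / 1000
  if (p >= 1)
    stop("rate_hz * dt_ms corresponds to >= 1 expected spike per bin; ",
         "use a smaller dt_ms")
  if (!is.null(seed)) set.seed(as.integer(seed))
  nbins <- as.integer(round(duration_ms / dt_ms))
  ev <- gen_poisson_cpp(seq_len(n_neurons), p, nbins)
  .spike_raster(ev$id, (ev$step + 1) * dt_ms, n_neurons, duration_ms)
}

.spike_raster <- function(id, time_ms, n_neurons, duration_ms) {
  structure(data.frame(id = as.integer(id), time_ms = time_ms),
            n_neurons = as.integer(n_neurons), duration_ms = duration_ms,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster: %d events, %d neurons, %.0f ms>\n", nrow(x),
              attr(x, "n_neurons"), attr(x, "duration_ms")))
  invisible(x)
}

#' Write a spike raster as two-column text
#'
#' @param raster A `spike_raster`.
#' @param path Output path; columns `id` and `time_ms`, tab-separated.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(as.data.frame(raster)[, c("id", "time_ms")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: events for a subset of input neurons over [t0, t1) as 0-based
# integrator steps (absolute)
.poisson_events <- function(ids, rate_hz, t0_ms, t1_ms, dt_ms) {
  p <- rate_hz * dt_ms / 1000
  if (p >= 1) stop("rate * dt >= 1: bin too coarse")
  nbins <- as.integer(round((t1_ms - t0_ms) / dt_ms))
  if (nbins <= 0 || length(ids) == 0 || rate_hz == 0)
    return(list(step = integer(0), id = integer(0)))
  ev <- gen_poisson_cpp(as.integer(ids), p, nbins)
  list(step = ev$step + as.integer(round(t0_ms / dt_ms)), id = ev$id)
}

# internal: constant-rate input schedule for a whole episode
.input_schedule_constant <- function(n_ext, rate_hz, duration_ms, dt_ms) {
  ev <- .poisson_events(seq_len(n_ext), rate_hz, 0, duration_ms, dt_ms)
  list(step = ev$step, id = ev$id, n_ext = n_ext, duration_ms = duration_ms,
       dt_ms = dt_ms)
}

# internal: merge event lists and sort by step (stable on id)
.merge_events <- function(...) {
  evs <- list(...)
  step <- unlist(lapply(evs, `[[`, "step"), use.names = FALSE)
  id <- unlist(lapply(evs, `[[`, "id"), use.names = FALSE)
  o <- order(step, id)
  list(step = as.integer(step[o]), id = as.integer(id[o]))
}
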