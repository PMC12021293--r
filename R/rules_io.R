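#' Serialize a plasticity rule to JSON
#'
#' Stores the space tag, the encoded parameter vector, the frozen-layer
#' seed (MLP space) and optional weight bounds, so a learned rule can be
#' reloaded for re-simulation or protocol visualization.
#'
#' @param rule A `plasticity_rule`.
#' @param path Output path (`.json`).
#' @param bounds Optional weight bounds stored alongside.
#' @return `path`, invisibly.
#' @export
write_rule <- function(rule, path, bounds = c(0, 10)) {
  obj <- list(space = rule_space(rule), theta = encode_theta(rule),
              bounds = bounds)
  if (inherits(rule, "mlp_rule")) obj$frozen_seed <- rule$frozen_seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a plasticity rule from JSON
#'
#' @param path A file written by [write_rule()].
#' @return The `plasticity_rule`, with attribute `bounds`.
#' @export
read_rule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- if (is.null(obj$frozen_seed)) 42L else as.integer(obj$frozen_seed)
  rule <- decode_theta(as.numeric(obj$theta), obj$space, frozen_seed = fs)
  attr(rule, "bounds") <- as.numeric(obj$bounds)
  rule
}
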