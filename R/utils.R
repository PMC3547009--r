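# Small shared helpers: seed fan-out, spherical geometry.

#' Derive a child seed from a master seed
#'
#' Stages of the pipeline draw their own seeds from a single master seed so
#' that each stage is individually reproducible. The scheme is a simple
#' splittable counter kept below 2^31.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (0, 1, 2, ...).
#' @return An integer seed.
#' @export
child_seed <- function(master, stage) {
  as.integer((as.double(master) * 1009 + as.double(stage) * 9973) %% 2147483647L)
}

## great-circle (angular) distance between rows of unit-vector matrices
angular_distance <- function(a, b) {
  d <- pmin(pmax(as.vector(a %*% b), -1), 1)
  acos(d)
}

## spherical linear interpolation between two unit vectors, fraction f in [0,1]
slerp <- function(p, q, f) {
  omega <- acos(min(max(sum(p * q), -1), 1))
  if (omega < 1e-12) return(p)
  (sin((1 - f) * omega) * p + sin(f * omega) * q) / sin(omega)
}

unit <- function(v) v / sqrt(sum(v^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
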