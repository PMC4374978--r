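#' Wrap angles to (-pi, pi]
#'
#' Maps arbitrary angles onto the principal interval used throughout the
#' package. The right-open convention of many wrapping helpers is avoided:
#' -pi wraps to +pi so every heading has a unique representation.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, in (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' Shortest-arc angular difference a - b
#'
#' @param a,b numeric vectors of angles in radians.
#' @return wrapped difference in (-pi, pi].
#' @export
angle_diff <- function(a, b) {
  wrap_angle(a - b)
}

#' Circular midpoint of two angles along the shortest arc
#'
#' Computed from the resultant of the two unit vectors, so the midpoint of
#' +3 and -3 rad is near pi, not 0. For exactly antipodal inputs the
#' resultant vanishes and the midpoint is taken at a + pi/2 for determinism.
#'
#' @param a,b numeric vectors of angles in radians.
#' @return numeric vector of midpoints in (-pi, pi].
#' @export
circular_midpoint <- function(a, b) {
  sx <- cos(a) + cos(b)
  sy <- sin(a) + sin(b)
  out <- atan2(sy, sx)
  degenerate <- sx == 0 & sy == 0
  if (any(degenerate)) {
    out[degenerate] <- wrap_angle(a[degenerate] + pi / 2)
  }
  wrap_angle(out)
}

# Deterministic small-integer seed derived from a base seed and a set of
# numeric tags; keeps derived seeds in 32-bit range.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed)
  for (v in tags) {
    h <- (h * 31 + abs(round(v * 1e4))) %% 214748329
  }
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
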