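#' Measurement with standard uncertainty
#'
#' Lightweight value-carrier used throughout the package: a numeric value, its
#' standard uncertainty (k = 1), the unit, and the provenance of the
#' uncertainty (how it was obtained: from a normal distribution, from a
#' rectangular/uniform range, or derived by propagation).
#'
#' @param value numeric value in `unit`.
#' @param u standard uncertainty (k = 1), same unit; must be >= 0.
#' @param unit unit string, e.g. `"mg/kg"`; purely descriptive.
#' @param dist one of `"derived"`, `"normal"`, `"rectangular"`.
#' @return An object of class `measurement`.
#' @examples
#' m <- measurement(33, 1.5, "g/kg", "normal")
#' expanded_u(m, k = 2)
#' @export
measurement <- function(value, u = 0, unit = "",
                        dist = c("derived", "normal", "rectangular")) {
  dist <- match.arg(dist)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u < 0)
    stop("standard uncertainty 'u' must be a single non-negative number")
  structure(list(value = value, u = u, unit = unit, dist = dist),
            class = "measurement")
}

#' @export
print.measurement <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.measurement <- function(x, digits = 4, ...) {
  out <- sprintf("%s +/- %s%s [%s]",
                 format(x$value, digits = digits),
                 format(x$u, digits = digits),
                 if (nzchar(x$unit)) paste0(" ", x$unit) else "",
                 x$dist)
  out
}

#' Test for measurement objects
#' @param x object.
#' @return `TRUE` for objects created by [measurement()].
#' @export
is.measurement <- function(x) inherits(x, "measurement")

#' Expanded uncertainty
#'
#' @param m a [measurement()].
#' @param k coverage factor (> 0); k = 2 gives approximately 95 % coverage
#'   for a normal output quantity.
#' @return `k * u`.
#' @export
expanded_u <- function(m, k = 2) {
  stopifnot(is.measurement(m), k > 0)
  k * m$u
}

#' Relative standard uncertainty
#'
#' @param m a [measurement()] with non-zero value.
#' @return `u / |value|` (dimensionless, k = 1).
#' @export
rel_u <- function(m) {
  stopifnot(is.measurement(m))
  if (m$value == 0) stop("relative uncertainty undefined for zero value")
  m$u / abs(m$value)
}

#' Midpoint and rectangular standard uncertainty of a range
#'
#' For a quantity only known to lie in `[min, max]`, the GUM convention is a
#' rectangular (uniform) distribution: the best estimate is the midpoint and
#' the standard uncertainty is the half-range divided by sqrt(3).
#'
#' @param min,max range bounds, `max >= min`.
#' @param unit unit string attached to the result.
#' @return A [measurement()] with `dist = "rectangular"`.
#' @examples
#' rectangular_u(18629, 22975, "g/mol") # 20802 +/- 1255
#' @export
rectangular_u <- function(min, max, unit = "") {
  stopifnot(is.numeric(min), is.numeric(max), length(min) == 1L,
            length(max) == 1L)
  if (max < min) stop("'max' must be >= 'min'")
  measurement((min + max) / 2, (max - min) / (2 * sqrt(3)), unit,
              "rectangular")
}
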