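#' Indenter (probe) geometry
#'
#' Defines the Hertzian exponent `n` and geometric constant `C_geom` such
#' that an elastic half-space responds with \eqn{F = C_{geom} E \delta^n}:
#' \describe{
#'   \item{cylinder}{flat-ended punch of radius `radius`; `n = 1`,
#'     `C = 2 R_cyl`.}
#'   \item{sphere}{radius `radius`, valid for depths well below the radius;
#'     `n = 3/2`, `C = 4 sqrt(R) / 3`.}
#'   \item{cone}{included half-angle `half_angle` (rad); `n = 2`,
#'     `C = 2 tan(half_angle) / pi`.}
#' }
#'
#' By default `C_geom` is used as printed above, so moduli recovered from
#' simulated curves match the model moduli directly.  With
#' `nu_correction = TRUE` the conventional experimental divisor
#' \eqn{1/(1-\nu^2)} is applied.
#'
#' @param shape `"cylinder"`, `"sphere"` or `"cone"`.
#' @param radius probe radius (m), for cylinder and sphere.
#' @param half_angle included half-angle (rad), for the cone.
#' @param nu Poisson's ratio of the sample (default 0.5, incompressible).
#' @param nu_correction logical; divide `C_geom` by `1 - nu^2`?
#' @return object of class `probe_geometry` with fields `shape`, `n`,
#'   `C_geom`, `nu`, `nu_correction` and the dimension parameter.
#' @examples
#' probe_geometry("sphere", radius = 5e-6)
#' @export
probe_geometry <- function(shape = c("cylinder", "sphere", "cone"),
                           radius = NULL, half_angle = NULL,
                           nu = 0.5, nu_correction = FALSE) {
  shape <- match.arg(shape)
  if (shape == "cone") {
    if (is.null(half_angle) || half_angle <= 0 || half_angle >= pi / 2)
      stop("cone requires 'half_angle' in (0, pi/2)")
    n <- 2
    C <- 2 * tan(half_angle) / pi
    dimension <- c(half_angle = half_angle)
  } else {
    if (is.null(radius) || radius <= 0)
      stop(shape, " requires a positive 'radius'")
    if (shape == "cylinder") {
      n <- 1
      C <- 2 * radius
    } else {
      n <- 1.5
      C <- 4 * sqrt(radius) / 3
    }
    dimension <- c(radius = radius)
  }
  if (nu_correction) C <- C / (1 - nu^2)
  structure(list(shape = shape, dimension = dimension, n = n, C_geom = C,
                 nu = nu, nu_correction = nu_correction),
            class = "probe_geometry")
}

check_probe_depth <- function(probe, delta_max) {
  if (probe$shape == "sphere" && delta_max > 0.1 * probe$dimension[["radius"]])
    warning("indentation depth exceeds 10% of the sphere radius; ",
            "the parabolic contact approximation degrades", call. = FALSE)
  invisible(NULL)
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("<probe_geometry>", x$shape, "\n")
  cat(sprintf("  %s = %g, n = %g, C_geom = %g%s\n",
              names(x$dimension), x$dimension, x$n, x$C_geom,
              if (x$nu_correction)
                sprintf(" (with 1/(1-nu^2), nu = %g)", x$nu) else ""))
  invisible(x)
}
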