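#' Displacement-controlled indentation history
#'
#' A single-maximum indentation ramp \eqn{\delta(t)}:
#' \describe{
#'   \item{`triangular`}{\eqn{\delta = vt} for \eqn{t \le t_m},
#'     \eqn{\delta = v(2t_m - t)} afterwards, with \eqn{v = \delta_{max}/t_m}.}
#'   \item{`sinusoidal`}{\eqn{\delta = A\sin(\omega t)} with
#'     \eqn{A = \delta_{max}} and \eqn{\omega = \pi/(2 t_m)}, so the maximum
#'     contact radius is reached at \eqn{t_m}; the same sine continues
#'     through retraction until the force vanishes or \eqn{\delta} returns to
#'     zero at \eqn{2 t_m}.}
#' }
#'
#' @param kind `"triangular"` or `"sinusoidal"`.
#' @param delta_max maximum indentation depth (m), > 0.
#' @param t_m time of maximum contact radius (s), > 0.
#' @return object of class `indentation_history` with fields `kind`,
#'   `delta_max`, `t_m`, and `v` (m/s) or `A` (m) and `omega` (rad/s).
#' @examples
#' h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
#' depth_and_rate(h, c(0.025, 0.075))
#' @export
indentation_history <- function(kind = c("triangular", "sinusoidal"),
                                delta_max, t_m) {
  kind <- match.arg(kind)
  if (!is.numeric(delta_max) || length(delta_max) != 1L || delta_max <= 0)
    stop("'delta_max' must be a positive number")
  if (!is.numeric(t_m) || length(t_m) != 1L || t_m <= 0)
    stop("'t_m' must be a positive number")
  h <- list(kind = kind, delta_max = delta_max, t_m = t_m)
  if (kind == "triangular") {
    h$v <- delta_max / t_m
  } else {
    h$A <- delta_max
    h$omega <- pi / (2 * t_m)
  }
  class(h) <- "indentation_history"
  h
}

#' Depth and rate of an indentation history
#'
#' Exact evaluation of \eqn{\delta(t)} and \eqn{d\delta/dt}.  At the
#' triangular turning point `t = t_m` the rate is two-valued; the `phase`
#' flag selects the one-sided limit (`"approach"` gives `+v`, `"retract"`
#' gives `-v`; the default `"auto"` uses the approach limit at `t_m`).
#'
#' @param history an [indentation_history()].
#' @param t times (s), >= 0.
#' @param phase `"auto"`, `"approach"` or `"retract"`.
#' @return list with numeric vectors `delta` (m) and `rate` (m/s).
#' @export
depth_and_rate <- function(history, t,
                           phase = c("auto", "approach", "retract")) {
  stopifnot(inherits(history, "indentation_history"))
  phase <- match.arg(phase)
  if (any(t < 0)) stop("'t' must be non-negative")
  t_m <- history$t_m
  if (history$kind == "triangular") {
    v <- history$v
    on_app <- if (phase == "retract") t < t_m else t <= t_m
    delta <- ifelse(on_app, v * t, v * (2 * t_m - t))
    rate <- ifelse(on_app, v, -v)
  } else {
    A <- history$A; w <- history$omega
    delta <- A * sin(w * t)
    rate <- A * w * cos(w * t)
  }
  list(delta = delta, rate = rate)
}

#' @export
print.indentation_history <- function(x, ...) {
  cat("<indentation_history>", x$kind, "\n")
  cat(sprintf("  delta_max = %g m, t_m = %g s\n", x$delta_max, x$t_m))
  if (x$kind == "triangular")
    cat(sprintf("  approach speed v = %g m/s\n", x$v))
  else
    cat(sprintf("  A = %g m, omega = %g rad/s\n", x$A, x$omega))
  invisible(x)
}
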