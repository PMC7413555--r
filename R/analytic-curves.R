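#' Closed-form indentation force curves
#'
#' Analytic solutions of the hereditary-integral equations for the cases
#' where they are elementary; these serve as oracles for the numerical
#' solver.  Supported combinations:
#' \describe{
#'   \item{spring (any probe, any ramp)}{\eqn{F = C E \delta(t)^n} throughout
#'     the cycle; \eqn{t_1(t) = 2t_m - t} (triangular) or
#'     \eqn{\pi/\omega - t} (sinusoidal) by symmetry of the depth history.}
#'   \item{dashpot (any probe, any ramp)}{\eqn{F = C\eta\, n\delta^{n-1}
#'     \dot\delta} on approach (delta-kernel collapse of the integral) and 0
#'     on retraction -- the contact is lost at the turning point.}
#'   \item{kelvin_voigt (any probe, triangular)}{approach
#'     \eqn{F = C(E_\infty \delta^n + \eta n v \delta^{n-1})}; Ting's
#'     root condition reduces to \eqn{\delta(t_1) = \delta(t) - v\tau_{KV}}, so
#'     \eqn{t_1 = 2t_m - t - \tau_{KV}} and
#'     \eqn{F_{retr} = C E_\infty (v t_1)^n}, detaching at
#'     \eqn{2 t_m - \tau_{KV}}.}
#'   \item{maxwell (cylinder, triangular)}{approach
#'     \eqn{F = C E_0 v \tau (1 - e^{-t/\tau})};
#'     \eqn{t_1 = t_m + \tau\log(2 - e^{(t-t_m)/\tau})};
#'     \eqn{F_{retr} = C E_0 v \tau (2 e^{-(t-t_m)/\tau} - 1 - e^{-t/\tau})},
#'     detaching at \eqn{t_m + \tau\log(2 - e^{-t_m/\tau})}.}
#' }
#'
#' @inheritParams simulate_curve
#' @return a `force_curve` object (see [simulate_curve()]).
#' @export
analytic_curve <- function(model, history, probe, n_steps = 1000L) {
  stopifnot(inherits(model, "relaxation_model"),
            inherits(history, "indentation_history"),
            inherits(probe, "probe_geometry"))
  n <- as.integer(n_steps)
  t_m <- history$t_m
  h <- t_m / n
  C <- probe$C_geom
  pn <- probe$n
  t_app <- h * (0:n)
  t_ret_full <- t_m + h * (0:n)

  case <- model$name
  if (case == "kelvin_voigt" && history$kind != "triangular")
    stop("analytic Kelvin-Voigt curve requires the triangular ramp")
  if (case == "maxwell" &&
      !(history$kind == "triangular" && probe$shape == "cylinder"))
    stop("analytic Maxwell curve requires the triangular ramp and a cylinder")

  da <- depth_and_rate(history, t_app, phase = "approach")

  if (case == "spring") {
    E <- model$params$E
    F_app <- C * E * da$delta^pn
    dr <- depth_and_rate(history, t_ret_full, phase = "retract")
    F_ret <- C * E * pmax(dr$delta, 0)^pn
    t1 <- if (history$kind == "triangular") 2 * t_m - t_ret_full
          else pi / history$omega - t_ret_full
    t_detach <- 2 * t_m
    ret <- list(t = t_ret_full, F = F_ret, t1 = pmax(t1, 0))
  } else if (case == "dashpot") {
    eta <- model$params$eta
    F_app <- C * eta * pn * da$delta^(pn - 1) * da$rate
    t_detach <- t_m
    ret <- list(t = numeric(0), F = numeric(0), t1 = numeric(0))
  } else if (case == "kelvin_voigt") {
    E_inf <- model$params$E_inf; eta <- model$params$eta
    v <- history$v
    tau <- eta / E_inf
    F_app <- C * (E_inf * da$delta^pn + eta * pn * v * da$delta^(pn - 1))
    t_detach <- max(2 * t_m - tau, t_m)
    keep <- t_ret_full < t_detach
    t1 <- 2 * t_m - t_ret_full[keep] - tau
    F_ret <- C * E_inf * (v * t1)^pn
    ret <- list(t = t_ret_full[keep], F = F_ret, t1 = t1)
  } else if (case == "maxwell") {
    E0 <- model$params$E0
    tau <- model$char_time[["tau_MW"]]
    v <- history$v
    F_app <- C * E0 * v * tau * (1 - exp(-t_app / tau))
    t_detach <- min(t_m + tau * log(2 - exp(-t_m / tau)), 2 * t_m)
    keep <- t_ret_full < t_detach
    tr <- t_ret_full[keep]
    t1 <- t_m + tau * log(2 - exp((tr - t_m) / tau))
    F_ret <- C * E0 * v * tau *
      (2 * exp(-(tr - t_m) / tau) - 1 - exp(-tr / tau))
    ret <- list(t = tr, F = pmax(F_ret, 0), t1 = pmax(t1, 0))
  } else {
    stop("no analytic solution catalogued for model '", case, "'")
  }

  if (length(ret$t) && abs(ret$t[length(ret$t)] - t_detach) < 1e-12 * t_m) {
    ret$t <- ret$t[-length(ret$t)]
    ret$F <- ret$F[-length(ret$F)]
    ret$t1 <- ret$t1[-length(ret$t1)]
  }
  t_ret <- c(ret$t, t_detach)
  F_ret <- c(ret$F, 0)
  t1 <- c(ret$t1, 0)
  d_ret <- pmax(depth_and_rate(history, t_ret, phase = "retract")$delta, 0)

  structure(list(
    t = c(t_app, t_ret),
    delta = c(da$delta, d_ret),
    force = c(F_app, F_ret),
    phase = c(rep("approach", n + 1L), rep("retract", length(t_ret))),
    t1 = c(rep(NA_real_, n + 1L), t1),
    t_m = t_m, t_detach = t_detach, t_ind = t_detach,
    model = model, probe = probe, history = history,
    n_steps = n, method = "analytic"
  ), class = "force_curve")
}
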