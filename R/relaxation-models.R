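#' Construct a viscoelastic relaxation model
#'
#' Builds one of the catalogued linear viscoelastic models as a relaxation
#' function \eqn{E(t)} split into a regular part \eqn{E_{reg}(t)} (evaluated by
#' [eval_relaxation()]) and the coefficient of a Dirac-delta term
#' \eqn{\eta\,\delta_D(t)} that free dashpots in parallel contribute (handled
#' analytically by the indentation solver).
#'
#' Catalogue (parameters in brackets; moduli in Pa, viscosities in Pa s,
#' times in s, fractional exponents unitless):
#' \describe{
#'   \item{`spring`}{\eqn{E(t) = E} \[`E`\].}
#'   \item{`dashpot`}{\eqn{E(t) = \eta\,\delta_D(t)} \[`eta`\].}
#'   \item{`kelvin_voigt`}{\eqn{E(t) = E_\infty + \eta\,\delta_D(t)}
#'     \[`E_inf`, `eta`\]; \eqn{\tau_{KV} = \eta/E_\infty}.}
#'   \item{`maxwell`}{\eqn{E(t) = E_0 e^{-t/\tau}} \[`E0`, `tau` or `eta`\];
#'     \eqn{\tau_{MW} = \eta/E_0}.}
#'   \item{`sls`}{standard linear solid,
#'     \eqn{E(t) = (E_0-E_\infty)e^{-t/\tau} + E_\infty}
#'     \[`E0`, `E_inf`, `tau` or `eta`\]; \eqn{\tau_{rel} = \eta/(E_0-E_\infty)},
#'     \eqn{\tau_{creep} = E_0\eta/(E_\infty(E_0-E_\infty))}.}
#'   \item{`gen_maxwell`}{generalized Maxwell,
#'     \eqn{E(t) = \sum_i E_{si} e^{-t/\tau_i} + E_\infty}
#'     \[`E_s` (vector), `tau` (vector), `E_inf`\].}
#'   \item{`springpot`}{power law \eqn{E(t) = E_{\alpha 1} t^{-\alpha}}
#'     \[`E_alpha1`, `alpha`\], with the reference time fixed at 1 s so that
#'     `E_alpha1` is the modulus at t = 1 s (use [rescale_springpot()] for
#'     other reference times).}
#'   \item{`fractional_kv`}{springpot parallel to a spring,
#'     \eqn{E(t) = E_{\alpha 1} t^{-\alpha} + E_\infty}
#'     \[`E_alpha1`, `alpha`, `E_inf`\];
#'     \eqn{\tau = (E_{\alpha 1}/E_\infty)^{1/\alpha}}.}
#'   \item{`springpot_spring_series`}{springpot in series with a spring,
#'     \eqn{E(t) = E_0\, ML_\alpha(-(E_0/E_{\alpha 1}) t^\alpha)}
#'     \[`E0`, `E_alpha1`, `alpha`\];
#'     \eqn{\tau = (E_{\alpha 1}/E_0)^{1/\alpha}}.}
#'   \item{`springpot_dashpot_parallel`}{\eqn{E(t) = E_{\alpha 1} t^{-\alpha} +
#'     \eta\,\delta_D(t)} \[`E_alpha1`, `alpha`, `eta`\].}
#'   \item{`springpot_dashpot_series`}{
#'     \eqn{E(t) = \eta^{\beta/(\beta-1)} E_{\beta 1}^{1/(1-\beta)} t^{-\beta}
#'     ML_{1-\beta,1-\beta}(-(E_{\beta 1}/\eta) t^{1-\beta})}
#'     \[`E_beta1`, `beta`, `eta`\].}
#'   \item{`two_springpots_parallel`}{\eqn{E(t) = E_{\alpha 1} t^{-\alpha} +
#'     E_{\beta 1} t^{-\beta}} \[`E_alpha1`, `alpha`, `E_beta1`, `beta`\],
#'     \eqn{\beta < \alpha};
#'     \eqn{\tau = (E_{\alpha 1}/E_{\beta 1})^{1/(\alpha-\beta)}}.}
#'   \item{`two_springpots_series`}{
#'     \eqn{E(t) = E_{\alpha 1}^{\beta/(\beta-\alpha)}
#'     E_{\beta 1}^{\alpha/(\alpha-\beta)} t^{-\beta}
#'     ML_{\alpha-\beta,1-\beta}(-(E_{\beta 1}/E_{\alpha 1}) t^{\alpha-\beta})}
#'     \[`E_alpha1`, `alpha`, `E_beta1`, `beta`\], \eqn{\beta < \alpha};
#'     \eqn{\tau = ((1-\alpha) E_{\alpha 1}/E_{\beta 1})^{1/(\alpha-\beta)}}.}
#'   \item{`fractional_sls`}{fractional Zener,
#'     \eqn{E(t) = (E_0-E_\infty) ML_\alpha(-(t/\tau)^\alpha) + E_\infty}
#'     \[`E0`, `E_inf`, `alpha`, and `E_alpha1` or `tau`\];
#'     \eqn{\tau = (E_{\alpha 1}/(E_0-E_\infty))^{1/\alpha}}.}
#'   \item{`fractional_sls_dashpot`}{springpot-dashpot series parallel to a
#'     spring \[`E_beta1`, `beta`, `eta`, `E_inf`\].}
#' }
#'
#' At the boundary exponents the fractional elements reduce to classical ones
#' (a springpot with exponent 1 is a dashpot, with exponent 0 a spring), so
#' `alpha = 1` and `beta = 0` are admitted for the series combinations where
#' the kernel stays well defined.
#'
#' @param name model name (see catalogue above).
#' @param ... named parameters, or a single named list.
#' @return an object of class `relaxation_model` with elements `name`,
#'   `params`, `delta_coeff` (Pa s), `E0`, `E_inf` (Pa; may be `Inf`/0),
#'   `char_time` (named numeric, s), and internal evaluators for the regular
#'   part and its running time integral.
#' @seealso [eval_relaxation()], [time_averaged_modulus()],
#'   [prony_approximation()]
#' @examples
#' m <- relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.01)
#' m$char_time
#' @export
relaxation_model <- function(name, ...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots)[1]))
    dots <- dots[[1]]
  p <- lapply(dots, function(x) if (is.numeric(x)) x else
    stop("model parameters must be numeric"))
  builder <- switch(name,
    spring                    = build_spring,
    dashpot                   = build_dashpot,
    kelvin_voigt              = build_kelvin_voigt,
    maxwell                   = build_maxwell,
    sls                       = build_sls,
    gen_maxwell               = build_gen_maxwell,
    springpot                 = build_springpot,
    fractional_kv             = build_fractional_kv,
    springpot_spring_series   = build_sp_spring_series,
    springpot_dashpot_parallel = build_sp_dash_parallel,
    springpot_dashpot_series  = build_sp_dash_series,
    two_springpots_parallel   = build_two_sp_parallel,
    two_springpots_series     = build_two_sp_series,
    fractional_sls            = build_fractional_sls,
    fractional_sls_dashpot    = build_fractional_sls_dashpot,
    stop("unknown model name: ", name)
  )
  m <- builder(p)
  m$name <- name
  m$params <- p
  class(m) <- "relaxation_model"
  m
}

need <- function(p, what, pos = TRUE) {
  v <- p[[what]]
  if (is.null(v)) stop("missing parameter '", what, "'")
  if (pos && any(v <= 0)) stop("parameter '", what, "' must be positive")
  v
}

frac_exponent <- function(p, what, lo = 0, hi = 1,
                          lo_open = TRUE, hi_open = TRUE) {
  a <- p[[what]]
  if (is.null(a)) stop("missing parameter '", what, "'")
  bad <- a < lo || a > hi || (lo_open && a == lo) || (hi_open && a == hi)
  if (bad) stop("parameter '", what, "' out of admissible range")
  a
}

new_model <- function(E_reg, cumE, delta_coeff = 0, E0, E_inf, char_time = NULL) {
  if (delta_coeff < 0) stop("delta coefficient must be non-negative")
  list(E_reg = E_reg, cumE = cumE, delta_coeff = delta_coeff,
       E0 = E0, E_inf = E_inf, char_time = char_time)
}

build_spring <- function(p) {
  E <- need(p, "E")
  new_model(function(t) rep(E, length(t)), function(t) E * t,
            E0 = E, E_inf = E)
}

build_dashpot <- function(p) {
  eta <- need(p, "eta")
  new_model(function(t) rep(0, length(t)), function(t) rep(0, length(t)),
            delta_coeff = eta, E0 = Inf, E_inf = 0)
}

build_kelvin_voigt <- function(p) {
  E_inf <- need(p, "E_inf"); eta <- need(p, "eta")
  new_model(function(t) rep(E_inf, length(t)), function(t) E_inf * t,
            delta_coeff = eta, E0 = Inf, E_inf = E_inf,
            char_time = c(tau_KV = eta / E_inf))
}

exp_tau <- function(p, Ediff, tau_name) {
  # tau directly, or via eta with the named convention
  if (!is.null(p$tau)) need(p, "tau") else need(p, "eta") / Ediff
}

build_maxwell <- function(p) {
  E0 <- need(p, "E0")
  tau <- exp_tau(p, E0)
  new_model(function(t) E0 * exp(-t / tau),
            function(t) E0 * tau * (1 - exp(-t / tau)),
            E0 = E0, E_inf = 0, char_time = c(tau_MW = tau))
}

build_sls <- function(p) {
  E0 <- need(p, "E0"); E_inf <- need(p, "E_inf")
  if (E_inf >= E0) stop("'E_inf' must be below 'E0'")
  tau <- exp_tau(p, E0 - E_inf)
  Es <- E0 - E_inf
  eta <- tau * Es
  new_model(function(t) Es * exp(-t / tau) + E_inf,
            function(t) Es * tau * (1 - exp(-t / tau)) + E_inf * t,
            E0 = E0, E_inf = E_inf,
            char_time = c(tau_rel = tau,
                          tau_creep = E0 * eta / (E_inf * Es)))
}

build_gen_maxwell <- function(p) {
  E_s <- p$E_s; tau <- need(p, "tau")
  # zero coefficients are legal (inactive terms, e.g. from a non-negative
  # least-squares fit), so only negatives are rejected
  if (is.null(E_s)) stop("missing parameter 'E_s'")
  if (any(E_s < 0)) stop("parameter 'E_s' must be non-negative")
  E_inf <- if (is.null(p$E_inf)) 0 else p$E_inf
  if (E_inf < 0) stop("'E_inf' must be non-negative")
  if (sum(E_s) + E_inf <= 0) stop("model must have positive stiffness")
  if (length(E_s) != length(tau)) stop("'E_s' and 'tau' lengths differ")
  new_model(
    function(t) colSums(E_s * exp(-outer(1 / tau, t))) + E_inf,
    function(t) colSums(E_s * tau * (1 - exp(-outer(1 / tau, t)))) + E_inf * t,
    E0 = sum(E_s) + E_inf, E_inf = E_inf,
    char_time = setNames(tau, paste0("tau", seq_along(tau))))
}

build_springpot <- function(p) {
  Ea <- need(p, "E_alpha1"); a <- frac_exponent(p, "alpha")
  new_model(function(t) Ea * t^(-a),
            function(t) Ea * t^(1 - a) / (1 - a),
            E0 = Inf, E_inf = 0, char_time = c(tau = 1))
}

build_fractional_kv <- function(p) {
  Ea <- need(p, "E_alpha1"); a <- frac_exponent(p, "alpha")
  E_inf <- need(p, "E_inf")
  new_model(function(t) Ea * t^(-a) + E_inf,
            function(t) Ea * t^(1 - a) / (1 - a) + E_inf * t,
            E0 = Inf, E_inf = E_inf,
            char_time = c(tau = (Ea / E_inf)^(1 / a)))
}

build_sp_spring_series <- function(p) {
  E0 <- need(p, "E0"); Ea <- need(p, "E_alpha1")
  a <- frac_exponent(p, "alpha", hi_open = FALSE)
  c0 <- E0 / Ea
  new_model(function(t) E0 * mittag_leffler(a, 1, -c0 * t^a),
            function(t) E0 * t * mittag_leffler(a, 2, -c0 * t^a),
            E0 = E0, E_inf = 0,
            char_time = c(tau = (Ea / E0)^(1 / a)))
}

build_sp_dash_parallel <- function(p) {
  Ea <- need(p, "E_alpha1"); a <- frac_exponent(p, "alpha")
  eta <- need(p, "eta")
  new_model(function(t) Ea * t^(-a),
            function(t) Ea * t^(1 - a) / (1 - a),
            delta_coeff = eta, E0 = Inf, E_inf = 0,
            char_time = c(tau = (eta / Ea)^(1 / (1 - a))))
}

# shared kernel for the springpot-in-series-with-dashpot branch:
#   E(t) = C t^(-b) ML_{1-b,1-b}(-k t^(1-b)),  C = eta^(b/(b-1)) Eb^(1/(1-b))
sp_dash_series_parts <- function(Eb, b, eta) {
  C <- eta^(b / (b - 1)) * Eb^(1 / (1 - b))
  k <- Eb / eta
  list(
    E_reg = function(t) C * t^(-b) * mittag_leffler(1 - b, 1 - b, -k * t^(1 - b)),
    cumE  = function(t) C * t^(1 - b) * mittag_leffler(1 - b, 2 - b, -k * t^(1 - b)),
    tau   = (eta / Eb)^(1 / (1 - b))
  )
}

build_sp_dash_series <- function(p) {
  Eb <- need(p, "E_beta1")
  b <- frac_exponent(p, "beta", lo_open = FALSE)
  eta <- need(p, "eta")
  parts <- sp_dash_series_parts(Eb, b, eta)
  new_model(parts$E_reg, parts$cumE,
            E0 = if (b > 0) Inf else Eb, E_inf = 0,
            char_time = c(tau = parts$tau))
}

build_two_sp_parallel <- function(p) {
  Ea <- need(p, "E_alpha1"); Eb <- need(p, "E_beta1")
  a <- frac_exponent(p, "alpha"); b <- frac_exponent(p, "beta")
  if (b >= a) stop("'beta' must be below 'alpha' for two-springpot models")
  new_model(function(t) Ea * t^(-a) + Eb * t^(-b),
            function(t) Ea * t^(1 - a) / (1 - a) + Eb * t^(1 - b) / (1 - b),
            E0 = Inf, E_inf = 0,
            char_time = c(tau = (Ea / Eb)^(1 / (a - b))))
}

build_two_sp_series <- function(p) {
  Ea <- need(p, "E_alpha1"); Eb <- need(p, "E_beta1")
  a <- frac_exponent(p, "alpha", hi_open = FALSE)
  b <- frac_exponent(p, "beta", lo_open = FALSE)
  if (b >= a) stop("'beta' must be below 'alpha' for two-springpot models")
  C <- Ea^(b / (b - a)) * Eb^(a / (a - b))
  k <- Eb / Ea
  new_model(
    function(t) C * t^(-b) * mittag_leffler(a - b, 1 - b, -k * t^(a - b)),
    function(t) C * t^(1 - b) * mittag_leffler(a - b, 2 - b, -k * t^(a - b)),
    E0 = if (b > 0) Inf else Eb, E_inf = 0,
    char_time = c(tau = ((1 - a) * Ea / Eb)^(1 / (a - b))))
}

build_fractional_sls <- function(p) {
  E_inf <- need(p, "E_inf")
  a <- frac_exponent(p, "alpha", hi_open = FALSE)
  E0 <- need(p, "E0")
  if (E_inf >= E0) stop("'E_inf' must be below 'E0'")
  Es <- E0 - E_inf
  tau <- if (!is.null(p$tau)) need(p, "tau")
         else (need(p, "E_alpha1") / Es)^(1 / a)
  new_model(
    function(t) Es * mittag_leffler(a, 1, -(t / tau)^a) + E_inf,
    function(t) Es * t * mittag_leffler(a, 2, -(t / tau)^a) + E_inf * t,
    E0 = E0, E_inf = E_inf, char_time = c(tau_fSLS = tau))
}

build_fractional_sls_dashpot <- function(p) {
  Eb <- need(p, "E_beta1")
  b <- frac_exponent(p, "beta", lo_open = FALSE)
  eta <- need(p, "eta"); E_inf <- need(p, "E_inf")
  parts <- sp_dash_series_parts(Eb, b, eta)
  new_model(function(t) parts$E_reg(t) + E_inf,
            function(t) parts$cumE(t) + E_inf * t,
            E0 = if (b > 0) Inf else Eb + E_inf, E_inf = E_inf,
            char_time = c(tau = parts$tau))
}

#' Evaluate the regular part of a relaxation function
#'
#' Returns \eqn{E_{reg}(t)} for `t > 0`.  A Dirac-delta term
#' (`model$delta_coeff`) is *not* included; the indentation solver adds it
#' analytically.
#'
#' @param model a [relaxation_model()].
#' @param t strictly positive times (s).
#' @return modulus values (Pa), same length as `t`.
#' @export
eval_relaxation <- function(model, t) {
  stopifnot(inherits(model, "relaxation_model"))
  if (any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be strictly positive and finite")
  model$E_reg(t)
}

# Running integral int_0^t E_reg(s) ds; closed form for every catalogued
# model (power, exponential, and t^b * ML_{a,b+1} kernels).
cum_relaxation <- function(model, t) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- model$cumE(t[pos])
  out
}

#' Time-averaged relaxation modulus
#'
#' Average of the relaxation function over the first quarter of the
#' indentation cycle,
#' \deqn{\langle E\rangle = \frac{1}{t_{ind}/4}\int_0^{t_{ind}/4} E(t)\,dt,}
#' which tracks the apparent Young's modulus obtained from a Hertzian fit of
#' the approach curve.  A Dirac term contributes
#' `delta_coeff / (t_ind/4)`.
#'
#' The integral uses the model's closed-form running integral when
#' `method = "exact"` (available for the whole catalogue) or adaptive
#' quadrature with an explicit split of the power-law endpoint singularity
#' when `method = "quadrature"`.
#'
#' @param model a [relaxation_model()].
#' @param t_ind indentation-cycle duration(s), s.
#' @param method `"exact"` (default) or `"quadrature"`.
#' @return average modulus (Pa), same length as `t_ind`.
#' @export
time_averaged_modulus <- function(model, t_ind,
                                  method = c("exact", "quadrature")) {
  stopifnot(inherits(model, "relaxation_model"))
  if (any(t_ind <= 0)) stop("'t_ind' must be positive")
  method <- match.arg(method)
  T4 <- t_ind / 4
  if (method == "exact") {
    I <- cum_relaxation(model, T4)
  } else {
    I <- vapply(T4, function(up) {
      # peel off a possible integrable singularity at 0+ by splitting the
      # domain; integrate() handles the decaying remainder
      lo <- up * 1e-8
      head_part <- tryCatch(
        integrate(function(s) model$E_reg(s), 0, lo,
                  rel.tol = 1e-9, subdivisions = 400L)$value,
        error = function(e) {
          # endpoint diverges like t^-a: estimate a locally and use the
          # power-law closed form on the head interval
          a <- -log(model$E_reg(lo) / model$E_reg(lo / 2)) / log(2)
          model$E_reg(lo) * lo / (1 - a)
        })
      # tail in log time: power-law stretches become slowly varying, so the
      # adaptive rule reaches its tolerance over the full decade span
      head_part + integrate(function(x) model$E_reg(exp(x)) * exp(x),
                            log(lo), log(up),
                            rel.tol = 1e-9, subdivisions = 400L)$value
    }, numeric(1))
  }
  (I + model$delta_coeff) / T4
}

#' Logarithmic slope of the time-averaged modulus
#'
#' Central finite difference of \eqn{d\ln\langle E\rangle / d\ln t_{ind}}
#' with a step ratio of 1.05.  Non-positive for every catalogued model; its
#' negated double approximates the normalized hysteresis area (see
#' [nha_slope_check()]).
#'
#' @inheritParams time_averaged_modulus
#' @return unitless slope(s), `<= 0` up to round-off.
#' @export
log_slope_time_average <- function(model, t_ind) {
  r <- 1.05
  up <- time_averaged_modulus(model, t_ind * r)
  dn <- time_averaged_modulus(model, t_ind / r)
  (log(up) - log(dn)) / (2 * log(r))
}

#' Rescale a springpot to another reference time
#'
#' The springpot catalogue entry stores `E_alpha1`, the modulus at t = 1 s.
#' Returns the equivalent coefficient for a reference time `tau_ref`,
#' i.e. `E_alpha(tau_ref) = E_alpha1 * tau_ref^alpha`.
#'
#' @param E_alpha1 modulus at 1 s (Pa).
#' @param alpha fractional exponent.
#' @param tau_ref new reference time (s).
#' @export
rescale_springpot <- function(E_alpha1, alpha, tau_ref) {
  if (tau_ref <= 0) stop("'tau_ref' must be positive")
  E_alpha1 * tau_ref^alpha
}

#' Prony series approximation of a relaxation function
#'
#' Fits a generalized Maxwell model
#' \eqn{\sum_i E_{si} e^{-t/\tau_i} + E_\infty} with `n_terms` log-spaced
#' relaxation times spanning `t_range` to the regular part of `model`,
#' by non-negative least squares on a 200-point log-uniform time grid with
#' rows weighted by `1/E(t)` (so the residual is relative).  This is the
#' standard input form for finite-element solvers.
#'
#' @param model a [relaxation_model()] finite on `t_range`.
#' @param n_terms number of exponential terms (>= 1).
#' @param t_range numeric length-2, `0 < t_lo < t_hi` (s).
#' @return a `gen_maxwell` [relaxation_model()]; attribute
#'   `max_rel_error` reports the maximum relative fit error on the grid.
#' @export
prony_approximation <- function(model, n_terms, t_range) {
  stopifnot(inherits(model, "relaxation_model"))
  if (n_terms < 1) stop("'n_terms' must be at least 1")
  if (length(t_range) != 2 || t_range[1] <= 0 || t_range[2] <= t_range[1])
    stop("'t_range' must satisfy 0 < t_lo < t_hi")
  tau <- 10^seq(log10(t_range[1]), log10(t_range[2]), length.out = n_terms)
  tg <- 10^seq(log10(t_range[1]), log10(t_range[2]), length.out = 200L)
  y <- eval_relaxation(model, tg)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("model is not finite and positive on 't_range'")
  A <- cbind(exp(-outer(tg, 1 / tau)), 1)
  w <- 1 / y
  fit <- pracma::lsqnonneg(A * w, y * w)
  cf <- fit$x
  yhat <- as.vector(A %*% cf)
  out <- relaxation_model("gen_maxwell",
                          E_s = cf[seq_len(n_terms)], tau = tau,
                          E_inf = cf[n_terms + 1])
  attr(out, "max_rel_error") <- max(abs(yhat - y) / y)
  out
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat("<relaxation_model>", x$name, "\n")
  cat("  params:",
      paste(names(x$params),
            vapply(x$params, function(v) paste(signif(v, 6), collapse = ","),
                   character(1)),
            sep = " = ", collapse = "; "), "\n")
  cat(sprintf("  E0 = %s Pa, E_inf = %s Pa, delta term = %g Pa s\n",
              format(x$E0), format(x$E_inf), x$delta_coeff))
  if (!is.null(x$char_time))
    cat("  characteristic time(s):",
        paste(names(x$char_time), signif(x$char_time, 6),
              sep = " = ", collapse = "; "), "s\n")
  invisible(x)
}
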