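#' Apparent Young's modulus from a fixed-exponent Hertzian fit
#'
#' Least-squares fit of \eqn{F = C_{geom}\, YM\, \delta^n} with the exponent
#' fixed by the probe geometry, over the approach segment only (the same
#' segment that the quarter-cycle time average of the relaxation function
#' describes).  The solution is closed form:
#' \eqn{YM = \sum F \delta^n / (C_{geom} \sum \delta^{2n})}.
#'
#' @param curve a `force_curve` (or anything [as.data.frame()]-compatible
#'   with columns `time_s`, `indentation_m`, `force_N`, `phase`).
#' @param probe a [probe_geometry()]; defaults to the probe stored in the
#'   curve.
#' @return apparent Young's modulus (Pa).
#' @export
hertz_fit <- function(curve, probe = curve$probe) {
  d <- as.data.frame(curve)
  app <- d$phase == "approach" & d$indentation_m > 0
  if (sum(app) < 20L) stop("need at least 20 approach samples with depth > 0")
  dn <- d$indentation_m[app]^probe$n
  den <- sum(dn^2)
  if (den == 0 || all(d$force_N[app] == 0))
    stop("degenerate approach segment")
  sum(d$force_N[app] * dn) / (probe$C_geom * den)
}

#' Free-exponent power-law fit of the approach curve
#'
#' Nonlinear least squares of \eqn{F = A\,\delta^m} with both `A` and `m`
#' free, on the approach segment; samples shallower than 1% of the maximum
#' depth are excluded (the log-domain leverage of near-contact points is
#' numerically unstable).  Initialized from a log-log linear regression.
#' For a Hertzian (elastic) curve `m` equals the probe exponent `n`; strong
#' relaxation lowers it by up to one.
#'
#' @inheritParams hertz_fit
#' @return fitted exponent (unitless).
#' @export
exponent_fit <- function(curve) {
  d <- as.data.frame(curve)
  app <- d$phase == "approach"
  dmax <- max(d$indentation_m[app])
  keep <- app & d$indentation_m >= 0.01 * dmax & d$force_N > 0
  x <- d$indentation_m[keep]; y <- d$force_N[keep]
  if (length(x) < 5L) stop("too few usable approach samples")
  if (is.unsorted(x)) stop("approach depth must be increasing")
  ll <- lm(log(y) ~ log(x))
  start <- list(A = exp(coef(ll)[[1]]), m = coef(ll)[[2]])
  fit <- tryCatch(
    nls(y ~ A * x^m, start = start, algorithm = "port",
        lower = c(A = 0, m = 0.01), control = list(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(start$m)
  coef(fit)[["m"]]
}

trapz_area <- function(x, y) abs(sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))

#' Normalized hysteresis area
#'
#' Area enclosed between the approach and retraction branches of the
#' force-indentation curve, divided by the area under the approach branch --
#' the fraction of the indentation work dissipated in the cycle.  0 for a
#' purely elastic response, 1 when all energy is lost (pure dashpot; the
#' retraction force beyond detachment counts as zero).  Results outside
#' `[0, 1]` (possible through discretization noise only) are clipped with a
#' warning.
#'
#' @inheritParams hertz_fit
#' @return NHA in `[0, 1]`.
#' @export
nha <- function(curve) {
  d <- as.data.frame(curve)
  app <- d$phase == "approach"
  if (!any(app) || !any(!app)) stop("curve must contain both phases")
  a_app <- trapz_area(d$indentation_m[app], d$force_N[app])
  if (a_app == 0) stop("zero area under the approach curve")
  a_ret <- trapz_area(d$indentation_m[!app], d$force_N[!app])
  val <- (a_app - a_ret) / a_app
  if (val < 0 || val > 1) {
    if (val < -1e-9 || val > 1 + 1e-9)
      warning("NHA of ", signif(val, 4), " clipped to [0, 1]")
    val <- min(max(val, 0), 1)
  }
  val
}

#' All three curve descriptors at once
#'
#' @inheritParams hertz_fit
#' @return object of class `curve_metrics`: `apparent_YM` (Pa), `NHA`,
#'   `exponent`, plus the Hertzian amplitude and fit residuals.
#' @export
curve_metrics <- function(curve, probe = curve$probe) {
  ym <- hertz_fit(curve, probe)
  ex <- exponent_fit(curve)
  d <- as.data.frame(curve)
  app <- d$phase == "approach"
  resid <- d$force_N[app] - probe$C_geom * ym * d$indentation_m[app]^probe$n
  structure(list(apparent_YM = ym, NHA = nha(curve), exponent = ex,
                 hertz_amplitude = probe$C_geom * ym,
                 hertz_rms_residual = sqrt(mean(resid^2))),
            class = "curve_metrics")
}

#' @export
print.curve_metrics <- function(x, ...) {
  cat(sprintf("apparent YM = %.6g Pa, NHA = %.4f, exponent = %.4f\n",
              x$apparent_YM, x$NHA, x$exponent))
  invisible(x)
}

#' Sweep of curve metrics over indentation time
#'
#' Simulates one full cycle per requested indentation time and extracts the
#' apparent Young's modulus, NHA and curve exponent.  The grid is the
#' nominal cycle duration \eqn{t_{ind} = 2 t_m}; the measured contact time
#' (detachment) is recorded per point.  The normalized time axis is
#' \eqn{\bar t = t_{ind}/\tau} with \eqn{\tau} the model's first
#' characteristic time.
#'
#' @inheritParams simulate_curve
#' @param kind ramp kind, `"triangular"` or `"sinusoidal"`.
#' @param t_ind indentation-cycle durations (s); log-spaced, at least 3.
#' @param delta_max maximum depth (m); curve shapes are depth-invariant
#'   within linear viscoelasticity, so this is presentation only.
#' @param normalize `"none"`, `"E0"`, `"E_inf"` or `"E0_minus_Einf"`:
#'   divisor for the reported `YM_norm` column (different summaries of the
#'   same model call for different normalizations).
#' @return object of class `indentation_sweep`: a data frame with columns
#'   `t_ind_s`, `t_norm`, `t_contact_s`, `YM_Pa`, `YM_norm`, `NHA`,
#'   `exponent`, with the model/probe/ramp stored as attributes.  Points
#'   whose simulation fails are reported as `NA` rows, not errors.
#' @export
sweep_indentation_time <- function(model, probe, kind = "triangular",
                                   t_ind, delta_max = 100e-9,
                                   n_steps = 400L,
                                   normalize = c("none", "E0", "E_inf",
                                                 "E0_minus_Einf")) {
  stopifnot(inherits(model, "relaxation_model"),
            inherits(probe, "probe_geometry"))
  normalize <- match.arg(normalize)
  if (length(t_ind) < 3L) stop("'t_ind' needs at least 3 grid points")
  if (is.unsorted(t_ind, strictly = TRUE))
    stop("'t_ind' must be strictly increasing")
  div <- switch(normalize,
                none = 1,
                E0 = model$E0,
                E_inf = model$E_inf,
                E0_minus_Einf = model$E0 - model$E_inf)
  if (!is.finite(div) || div <= 0) {
    if (normalize != "none")
      warning("normalization constant is not finite and positive; ",
              "reporting raw YM")
    div <- 1
  }
  tau <- if (is.null(model$char_time)) 1 else model$char_time[[1]]
  rows <- lapply(t_ind, function(T) {
    out <- tryCatch({
      h <- indentation_history(kind, delta_max = delta_max, t_m = T / 2)
      fc <- simulate_curve(model, h, probe, n_steps = n_steps)
      m <- curve_metrics(fc, probe)
      c(fc$t_detach, m$apparent_YM, m$NHA, m$exponent)
    }, error = function(e) {
      warning("sweep point t_ind = ", signif(T, 4), " failed: ",
              conditionMessage(e), call. = FALSE)
      rep(NA_real_, 4)
    })
    data.frame(t_ind_s = T, t_norm = T / tau, t_contact_s = out[1],
               YM_Pa = out[2], YM_norm = out[2] / div,
               NHA = out[3], exponent = out[4])
  })
  res <- do.call(rbind, rows)
  attr(res, "model") <- model
  attr(res, "probe") <- probe
  attr(res, "kind") <- kind
  attr(res, "normalize") <- normalize
  class(res) <- c("indentation_sweep", "data.frame")
  res
}

#' Apparent modulus versus time-averaged relaxation function
#'
#' Per-point relative deviation between the apparent Young's modulus of a
#' sweep and the quarter-cycle time average \eqn{\langle E\rangle(t_{ind})}
#' of the relaxation function ([time_averaged_modulus()]), which the
#' Hertzian fit of the approach curve tracks closely for all catalogued
#' models.
#'
#' @param model the [relaxation_model()] the sweep was computed for.
#' @param sweep an [sweep_indentation_time()] result.
#' @return numeric vector, \eqn{|YM - \langle E\rangle| / \langle E\rangle}
#'   per sweep point.
#' @export
eq_average_check <- function(model, sweep) {
  stopifnot(inherits(sweep, "indentation_sweep"))
  avg <- time_averaged_modulus(model, sweep$t_ind_s)
  abs(sweep$YM_Pa - avg) / avg
}

#' NHA versus doubled log-slope of the time-averaged modulus
#'
#' Pairs the observed NHA with \eqn{-2\, d\ln\langle E\rangle/d\ln t_{ind}}
#' per sweep point.  The anchors: a flat (elastic) region gives slope 0 and
#' NHA 0; the steepest admissible decay (slope magnitude 1, the dashpot)
#' gives NHA 1.  In between the doubled slope approximates the NHA only
#' loosely; this function supplies the pairs for plotting or tolerance
#' checks.
#'
#' @inheritParams eq_average_check
#' @return data frame with `t_ind_s`, `NHA`, `doubled_slope`.
#' @export
nha_slope_check <- function(model, sweep) {
  stopifnot(inherits(sweep, "indentation_sweep"))
  sl <- log_slope_time_average(model, sweep$t_ind_s)
  data.frame(t_ind_s = sweep$t_ind_s, NHA = sweep$NHA,
             doubled_slope = -2 * sl)
}

#' Add reproducible Gaussian force noise to a curve
#'
#' Test fixture generator for analysis-robustness checks: adds i.i.d.
#' Gaussian noise to the force channel only.  The RNG state is isolated, so
#' a fixed seed always reproduces the same curve and the caller's RNG stream
#' is untouched.
#'
#' @param curve a `force_curve`.
#' @param force_noise_sd standard deviation of the added noise (N), >= 0.
#' @param seed integer seed.
#' @return the noisy `force_curve`; `noise_sd` and `noise_seed` are recorded.
#' @export
add_noise <- function(curve, force_noise_sd, seed = 1L) {
  stopifnot(inherits(curve, "force_curve"))
  if (force_noise_sd < 0) stop("'force_noise_sd' must be non-negative")
  if (force_noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    curve$force <- curve$force + stats::rnorm(length(curve$force),
                                              sd = force_noise_sd)
  }
  curve$noise_sd <- force_noise_sd
  curve$noise_seed <- seed
  curve
}

#' @export
plot.indentation_sweep <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$t_norm, x$YM_norm, log = "xy", type = "b",
       xlab = expression(t[ind] / tau), ylab = "apparent YM (normalized)", ...)
  plot(x$t_norm, x$NHA, log = "x", type = "b", ylim = c(0, 1),
       xlab = expression(t[ind] / tau), ylab = "NHA", ...)
  plot(x$t_norm, x$exponent, log = "x", type = "b",
       xlab = expression(t[ind] / tau), ylab = "curve exponent", ...)
  invisible(x)
}
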