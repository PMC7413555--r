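#' Simulate a full indentation cycle (Ting solver)
#'
#' Computes the force history of a displacement-controlled indentation cycle
#' on a linear viscoelastic half-space.  The approach phase evaluates the
#' Lee-Radok hereditary integral
#' \deqn{F(t) = C_{geom} \int_0^t E(t-\xi)\,
#'   \frac{\partial \delta^n}{\partial \xi}\, f_{BEC}(\delta)\, d\xi,}
#' and the retraction phase (shrinking contact radius) Ting's solution, which
#' truncates the integral at the auxiliary time \eqn{t_1(t)} defined by
#' \deqn{\int_{t_1(t)}^{t} E(t-\xi) \frac{\partial\delta}{\partial\xi} d\xi = 0.}
#'
#' Numerics: product integration on a uniform grid of `n_steps` per phase --
#' within each step the rate \eqn{\partial\delta^n/\partial\xi} is frozen at
#' its midpoint value and the kernel is integrated exactly through the
#' closed-form running integral of \eqn{E_{reg}}, so integrable
#' \eqn{t^{-\alpha}} kernel singularities cost no accuracy.  A Dirac term
#' \eqn{\eta\,\delta_D} contributes \eqn{\eta\, d\delta^n/dt} at the running
#' endpoint with full weight (causal limit), which reproduces the initial
#' force jump of Kelvin-Voigt materials under a cylindrical punch and the
#' force drop at the triangular turning point.  \eqn{t_1(t)} is solved by
#' bracketed root finding, warm-started from the previous sample (it is
#' non-increasing).  Detachment (`t_detach`) is the time at which no root
#' remains, located by linear interpolation; the force is identically zero
#' beyond it and the grid is truncated there.
#'
#' @param model a [relaxation_model()].
#' @param history an [indentation_history()].
#' @param probe a [probe_geometry()].
#' @param n_steps grid points per phase (>= 100; default 1000).
#' @param f_bec optional bottom-effect correction: a function of the depth
#'   (m) returning a multiplicative factor; default `NULL` means 1 (sample
#'   much thicker than the contact).
#' @param method `"ting"` (default) or `"lee_radok"`, which continues the
#'   approach integral through retraction (exact for the cylinder, an
#'   approximation otherwise).
#' @return object of class `force_curve`: vectors `t` (s), `delta` (m),
#'   `force` (N), `phase` (`"approach"`/`"retract"`), `t1` (s; `NA` during
#'   approach), and scalars `t_m`, `t_detach`, `t_ind` (= contact duration
#'   `t_detach`) plus the inputs as metadata.
#' @examples
#' m <- relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.01)
#' h <- indentation_history("triangular", 100e-9, 0.05)
#' p <- probe_geometry("sphere", radius = 5e-6)
#' fc <- simulate_curve(m, h, p, n_steps = 200)
#' fc
#' @export
simulate_curve <- function(model, history, probe, n_steps = 1000L,
                           f_bec = NULL, method = c("ting", "lee_radok")) {
  stopifnot(inherits(model, "relaxation_model"),
            inherits(history, "indentation_history"),
            inherits(probe, "probe_geometry"))
  method <- match.arg(method)
  if (n_steps < 100) stop("'n_steps' must be at least 100")
  n_steps <- as.integer(n_steps)
  check_probe_depth(probe, history$delta_max)
  fb <- if (is.null(f_bec)) function(d) 1 else f_bec

  n <- n_steps
  t_m <- history$t_m
  h <- t_m / n
  C <- probe$C_geom
  pn <- probe$n
  eta_d <- model$delta_coeff

  # kernel running integral at grid lags, G(k h), k = 1..2n
  Gk <- cum_relaxation(model, h * seq_len(2L * n))
  dG <- diff(c(0, Gk))
  Gfun <- function(s) cum_relaxation(model, s)

  # midpoint rates across both phases
  mid <- (seq_len(2L * n) - 0.5) * h
  dr_mid <- depth_and_rate(history, mid)
  rate_mid <- dr_mid$rate
  rn_mid <- pn * dr_mid$delta^(pn - 1) * dr_mid$rate * vapply(dr_mid$delta, fb, 1)

  rn_at <- function(t, phase) {
    d <- depth_and_rate(history, t, phase = phase)
    pn * d$delta^(pn - 1) * d$rate * fb(d$delta)
  }

  # ---- approach ----
  t_app <- h * (0:n)
  F_app <- numeric(n + 1L)
  F_app[1L] <- C * eta_d * rn_at(0, "approach")
  for (i in seq_len(n))
    F_app[i + 1L] <- C * (sum(rn_mid[seq_len(i)] * dG[i:1]) +
                          eta_d * rn_at(i * h, "approach"))

  # ---- retraction ----
  t1_vec <- numeric(0)
  F_ret <- numeric(0)
  t_ret <- numeric(0)
  t_detach <- 2 * t_m
  detached <- FALSE

  # the retraction branch starts at t_m with the right-limit force (the
  # Dirac term switches sign there, producing the turning-point force drop)
  if (method == "lee_radok") {
    for (m in 0:n) {
      M <- n + m
      Fm <- C * (sum(rn_mid[seq_len(M)] * dG[M:1]) +
                 eta_d * rn_at(M * h, "retract"))
      if (Fm <= 0) {
        if (m == 0L) {
          t_detach <- t_m
        } else {
          Fprev <- F_ret[length(F_ret)]
          tprev <- t_ret[length(t_ret)]
          t_detach <- if (Fprev > Fm) tprev + (M * h - tprev) *
            Fprev / (Fprev - Fm) else tprev
        }
        detached <- TRUE
        break
      }
      t_ret <- c(t_ret, M * h)
      F_ret <- c(F_ret, Fm)
      t1_vec <- c(t1_vec, NA_real_)
    }
  } else {
    t1_prev <- t_m
    c0_prev <- NA_real_   # hereditary residual at t1 = 0, previous sample
    for (m in 0:n) {
      M <- n + m
      t_cur <- M * h
      contrib <- rate_mid[seq_len(M)] * dG[M:1]
      ssum <- c(rev(cumsum(rev(contrib))), 0)
      dterm <- eta_d * depth_and_rate(history, t_cur, phase = "retract")$rate

      phi <- function(t1) {
        if (t1 <= 0) return(dterm + ssum[1L])
        k0 <- floor(t1 / h + 1e-12)
        if (abs(t1 - k0 * h) < 1e-12 * t_m)
          return(dterm + ssum[k0 + 1L])
        up <- (k0 + 1) * h
        rmid <- depth_and_rate(history, (t1 + up) / 2)$rate
        # grid lag M - k0 - 1 can be 0 (t1 inside the interval ending at
        # t_cur - h when m = 0), where the running integral is 0 by definition
        G_lag <- if (M - k0 - 1L > 0L) Gk[M - k0 - 1L] else 0
        dterm + ssum[k0 + 2L] +
          rmid * (Gfun(t_cur - t1) - G_lag)
      }

      f0 <- phi(0)
      if (f0 <= 0) {
        # contact lost between the previous sample and this one
        t_detach <- if (m == 0L || !is.finite(c0_prev) || c0_prev <= 0) {
          t_m
        } else {
          (t_cur - h) + h * c0_prev / (c0_prev - f0)
        }
        detached <- TRUE
        break
      }
      upper <- min(t1_prev, t_m)
      fu <- phi(upper)
      if (fu > 0) { upper <- t_m; fu <- phi(upper) }
      t1_cur <- if (fu >= 0) upper else
        uniroot(phi, lower = 0, upper = upper, f.lower = f0, f.upper = fu,
                tol = h * 1e-8)$root

      # force with the integral truncated at t1
      k1 <- floor(t1_cur / h + 1e-12)
      Fm <- sum(rn_mid[seq_len(k1)] * dG[M - seq_len(k1) + 1L])
      if (t1_cur - k1 * h > 1e-12 * t_m) {
        rnp <- rn_at((k1 * h + t1_cur) / 2, "approach")
        G_lag <- if (M - k1 > 0L) Gk[M - k1] else 0
        Fm <- Fm + rnp * (G_lag - Gfun(t_cur - t1_cur))
      }
      Fm <- C * Fm

      t_ret <- c(t_ret, t_cur)
      F_ret <- c(F_ret, max(Fm, 0))
      t1_vec <- c(t1_vec, t1_cur)
      t1_prev <- t1_cur
      c0_prev <- f0
    }
  }

  if (detached || length(t_ret) == 0L || max(t_ret) < 2 * t_m) {
    if (!detached) t_detach <- 2 * t_m
    t_ret <- c(t_ret, t_detach)
    F_ret <- c(F_ret, 0)
    t1_vec <- c(t1_vec, if (method == "ting") 0 else NA_real_)
  } else {
    t_detach <- 2 * t_m
  }

  d_app <- depth_and_rate(history, t_app, phase = "approach")$delta
  d_ret <- pmax(depth_and_rate(history, t_ret, phase = "retract")$delta, 0)

  structure(list(
    t = c(t_app, t_ret),
    delta = c(d_app, d_ret),
    force = c(F_app, F_ret),
    phase = c(rep("approach", n + 1L), rep("retract", length(t_ret))),
    t1 = c(rep(NA_real_, n + 1L), t1_vec),
    t_m = t_m, t_detach = t_detach, t_ind = t_detach,
    model = model, probe = probe, history = history,
    n_steps = n, method = method
  ), class = "force_curve")
}

#' Approach-phase force on an arbitrary time grid
#'
#' Reference implementation of the Lee-Radok integral on a user-supplied
#' ascending grid in `[0, t_m]` (the grid itself is the product-integration
#' partition).  [simulate_curve()] provides the fast uniform-grid path.
#'
#' @inheritParams simulate_curve
#' @param t_grid ascending times (s) within `[0, t_m]`.
#' @return force (N) at `t_grid`.
#' @export
approach_force <- function(model, history, probe, t_grid, f_bec = NULL) {
  stopifnot(inherits(model, "relaxation_model"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly ascending")
  if (any(t_grid < 0) || any(t_grid > history$t_m + 1e-12 * history$t_m))
    stop("'t_grid' must lie within [0, t_m]")
  fb <- if (is.null(f_bec)) function(d) 1 else f_bec
  pn <- probe$n
  knots <- unique(c(0, t_grid))
  rn_at <- function(t) {
    d <- depth_and_rate(history, t, phase = "approach")
    pn * d$delta^(pn - 1) * d$rate * vapply(d$delta, fb, 1)
  }
  vapply(t_grid, function(tt) {
    xi <- knots[knots <= tt + 1e-15]
    if (length(xi) < 2L || tt == 0)
      return(probe$C_geom * model$delta_coeff * rn_at(tt))
    lo <- xi[-length(xi)]; up <- xi[-1L]
    rn <- rn_at((lo + up) / 2)
    ker <- cum_relaxation(model, tt - lo) - cum_relaxation(model, tt - up)
    probe$C_geom * (sum(rn * ker) + model$delta_coeff * rn_at(tt))
  }, numeric(1))
}

# Ting residual int_{t1}^{t} E(t - xi) d delta/d xi d xi (+ Dirac term at
# xi = t) evaluated by product integration on a uniform sub-partition.
ting_residual <- function(model, history, t, t1, n_sub) {
  k <- max(2L, ceiling((t - t1) / (history$t_m / n_sub)))
  xi <- seq(t1, t, length.out = k + 1L)
  # split at the turning point: the rate is discontinuous there, and a
  # midpoint straddling it would cost one full order of accuracy
  t_m <- history$t_m
  if (t1 < t_m && t_m < t) xi <- sort(unique(c(xi, t_m)))
  lo <- xi[-length(xi)]; up <- xi[-1L]
  r <- depth_and_rate(history, (lo + up) / 2)$rate
  ker <- cum_relaxation(model, t - lo) - cum_relaxation(model, t - up)
  sum(r * ker) +
    model$delta_coeff * depth_and_rate(history, t, phase = "retract")$rate
}

#' Auxiliary time map t1(t) of Ting's solution
#'
#' For each retraction time `t`, finds the approach time `t1(t)` with the
#' same contact area, i.e. the root of the hereditary-integral condition
#' above.  `t1` is non-increasing, equals `t_m` at `t = t_m`, and reaches 0
#' at the detachment time, after which the force is identically zero.
#'
#' @inheritParams simulate_curve
#' @param retraction_times ascending times in `(t_m, 2 t_m]` (s).
#' @param n_steps sub-partition resolution (default 1000 intervals per
#'   phase duration).
#' @return list with `t1` (s; `NA` beyond detachment) and `t_detach` (s).
#' @export
t1_function <- function(model, history, retraction_times, n_steps = 1000L) {
  t_m <- history$t_m
  if (any(retraction_times <= t_m) || any(retraction_times > 2 * t_m))
    stop("'retraction_times' must lie in (t_m, 2*t_m]")
  if (is.unsorted(retraction_times, strictly = TRUE))
    stop("'retraction_times' must be strictly ascending")
  t1 <- rep(NA_real_, length(retraction_times))
  t_detach <- NA_real_
  prev <- t_m
  prev_t <- t_m
  for (i in seq_along(retraction_times)) {
    tt <- retraction_times[i]
    f0 <- ting_residual(model, history, tt, 0, n_steps)
    if (f0 <= 0) {
      t_detach <- tryCatch(
        uniroot(function(s) ting_residual(model, history, s, 0, n_steps),
                lower = prev_t, upper = tt, tol = t_m / n_steps * 1e-4)$root,
        error = function(e) prev_t)
      break
    }
    fu <- ting_residual(model, history, tt, prev, n_steps)
    up <- prev
    if (fu > 0) { up <- t_m; fu <- ting_residual(model, history, tt, t_m, n_steps) }
    t1[i] <- if (fu >= 0) up else
      uniroot(function(s) ting_residual(model, history, tt, s, n_steps),
              lower = 0, upper = up, f.lower = f0, f.upper = fu,
              tol = t_m / n_steps * 1e-4)$root
    prev <- t1[i]
    prev_t <- tt
  }
  if (is.na(t_detach) && !anyNA(t1)) {
    # contact survived the whole grid; detachment may still occur between
    # the last sample and the end of the cycle
    f_end <- ting_residual(model, history, 2 * t_m, 0, n_steps)
    t_detach <- if (f_end > 0) 2 * t_m else
      uniroot(function(s) ting_residual(model, history, s, 0, n_steps),
              lower = prev_t, upper = 2 * t_m,
              tol = t_m / n_steps * 1e-4)$root
  }
  list(t1 = t1, t_detach = t_detach)
}

#' Retraction-phase force on an arbitrary time grid
#'
#' Ting retraction force: the approach-phase integral truncated at
#' `t1(t)` (from [t1_function()] on the same grid).  Zero at and beyond
#' detachment.
#'
#' @inheritParams simulate_curve
#' @param t_grid retraction times (s).
#' @param t1_map result of [t1_function()] for `t_grid`.
#' @return force (N) at `t_grid`.
#' @export
retraction_force <- function(model, history, probe, t_grid, t1_map,
                             f_bec = NULL, n_steps = 1000L) {
  fb <- if (is.null(f_bec)) function(d) 1 else f_bec
  pn <- probe$n
  t1 <- t1_map$t1
  if (length(t1) != length(t_grid)) stop("'t1_map' does not match 't_grid'")
  vapply(seq_along(t_grid), function(i) {
    if (is.na(t1[i]) || t1[i] <= 0) return(0)
    tt <- t_grid[i]
    k <- max(2L, ceiling(t1[i] / (history$t_m / n_steps)))
    xi <- seq(0, t1[i], length.out = k + 1L)
    lo <- xi[-length(xi)]; up <- xi[-1L]
    d <- depth_and_rate(history, (lo + up) / 2, phase = "approach")
    rn <- pn * d$delta^(pn - 1) * d$rate * vapply(d$delta, fb, 1)
    ker <- cum_relaxation(model, tt - lo) - cum_relaxation(model, tt - up)
    max(probe$C_geom * sum(rn * ker), 0)
  }, numeric(1))
}

#' @export
print.force_curve <- function(x, ...) {
  cat("<force_curve>", x$model$name, "model,", x$probe$shape, "probe,",
      x$history$kind, "ramp\n")
  cat(sprintf("  %d samples, t_m = %g s, contact time t_ind = %g s (%.3g t_m)\n",
              length(x$t), x$t_m, x$t_detach, x$t_detach / x$t_m))
  cat(sprintf("  max depth %g m, max force %g N, solver: %s\n",
              max(x$delta), max(x$force), x$method))
  invisible(x)
}

#' @export
as.data.frame.force_curve <- function(x, row.names = NULL, optional = FALSE,
                                      normalized = FALSE, ...) {
  d <- data.frame(time_s = x$t, indentation_m = x$delta, force_N = x$force,
                  phase = x$phase, stringsAsFactors = FALSE)
  if (normalized) {
    d$indentation_norm <- x$delta / max(x$delta)
    d$force_norm <- x$force / max(x$force)
  }
  d
}

#' @export
plot.force_curve <- function(x, normalized = FALSE, ...) {
  d <- as.data.frame(x, normalized = normalized)
  if (normalized) {
    xx <- d$indentation_norm; yy <- d$force_norm
    xl <- expression(delta / delta[max]); yl <- expression(F / F[max])
  } else {
    xx <- d$indentation_m * 1e9; yy <- d$force_N * 1e9
    xl <- "indentation (nm)"; yl <- "force (nN)"
  }
  app <- d$phase == "approach"
  plot(xx[app], yy[app], type = "l", xlab = xl, ylab = yl,
       xlim = range(xx), ylim = range(yy), ...)
  lines(xx[!app], yy[!app], col = 2)
  legend("topleft", c("approach", "retraction"), col = c(1, 2), lty = 1,
         bty = "n")
  invisible(x)
}
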