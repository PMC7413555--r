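# simulate_curve() and t1_function() against the closed-form oracles.

test_that("elastic curves match the closed form for every probe and ramp", {
  m <- relaxation_model("spring", E = 1000)
  for (kind in c("triangular", "sinusoidal")) {
    h <- indentation_history(kind, delta_max = 100e-9, t_m = 0.05)
    for (p in study_probes()) {
      fc <- simulate_curve(m, h, p, n_steps = 400)
      ac <- analytic_curve(m, h, p, n_steps = 400)
      expect_lt(curve_error(fc, ac), 1e-4,
                label = paste("spring", kind, p$shape))
      # full-cycle contact: detachment at the end of the ramp
      expect_equal(fc$t_detach, 0.1, tolerance = 1e-6)
    }
  }
})

test_that("elastic t1 map is the mirror time of equal depth", {
  m <- relaxation_model("spring", E = 1000)
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  tr <- seq(0.055, 0.095, by = 0.005)
  t1 <- t1_function(m, h, tr, n_steps = 400)
  expect_equal(t1$t1, 0.1 - tr, tolerance = 1e-6)
  expect_equal(t1$t_detach, 0.1, tolerance = 1e-4)
})

test_that("dashpot: force is rate-borne on approach and contact breaks at t_m", {
  m <- relaxation_model("dashpot", eta = 10)
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  for (p in study_probes()) {
    fc <- simulate_curve(m, h, p, n_steps = 300)
    ac <- analytic_curve(m, h, p, n_steps = 300)
    expect_lt(curve_error(fc, ac), 1e-9, label = p$shape)
    expect_equal(fc$t_detach, 0.05)
    expect_true(all(fc$force[fc$phase == "retract"] == 0))
  }
})

test_that("Kelvin-Voigt matches its closed form, jump and early detachment", {
  tau <- 0.01
  m <- relaxation_model("kelvin_voigt", E_inf = 1000, eta = 1000 * tau)
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  for (p in study_probes()) {
    fc <- simulate_curve(m, h, p, n_steps = 400)
    ac <- analytic_curve(m, h, p, n_steps = 400)
    expect_lt(curve_error(fc, ac), 1e-4, label = p$shape)
    expect_equal(fc$t_detach, 0.1 - tau, tolerance = 1e-4)
  }
  # cylinder only: finite force jump C eta v at first touch, and a drop of
  # twice that at the turning point (the Dirac term switches sign)
  cyl <- study_probes()$cylinder
  fc <- simulate_curve(m, h, cyl, n_steps = 400)
  jump <- cyl$C_geom * 1000 * tau * h$v
  expect_equal(fc$force[1], jump, tolerance = 1e-12)
  i_app_end <- max(which(fc$phase == "approach"))
  expect_equal(fc$force[i_app_end] - fc$force[i_app_end + 1L], 2 * jump,
               tolerance = 1e-9)
})

test_that("Maxwell under a flat punch matches its closed form", {
  m <- relaxation_model("maxwell", E0 = 1000, tau = 0.02)
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  p <- study_probes()$cylinder
  fc <- simulate_curve(m, h, p, n_steps = 400)
  ac <- analytic_curve(m, h, p, n_steps = 400)
  expect_lt(curve_error(fc, ac), 1e-9)
  expect_equal(fc$t_detach, 0.05 + 0.02 * log(2 - exp(-0.05 / 0.02)),
               tolerance = 1e-5)
  # t1 map and detachment from the standalone root finder
  tr <- fc$t[fc$phase == "retract" & fc$t < fc$t_detach & fc$t > fc$t_m]
  t1 <- t1_function(m, h, tr, n_steps = 400)
  expect_equal(t1$t1, 0.05 + 0.02 * log(2 - exp((tr - 0.05) / 0.02)),
               tolerance = 1e-5)
  expect_equal(t1$t_detach, 0.05 + 0.02 * log(2 - exp(-0.05 / 0.02)),
               tolerance = 1e-5)
})

test_that("t1 is non-increasing and bracketed by [0, t_m] for all models", {
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  p <- study_probes()$sphere
  for (m in list(relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.02),
                 relaxation_model("springpot", E_alpha1 = 1000, alpha = 0.5),
                 relaxation_model("fractional_sls_dashpot", E_beta1 = 1000,
                                  beta = 0.3, eta = 1000, E_inf = 300))) {
    fc <- simulate_curve(m, h, p, n_steps = 300)
    t1 <- fc$t1[fc$phase == "retract"]
    expect_true(all(t1 >= 0 & t1 <= 0.05 + 1e-12), info = m$name)
    expect_true(all(diff(t1) <= 1e-12), info = m$name)
  }
})

test_that("retraction force never exceeds the approach force at equal depth", {
  # the relaxation-induced hysteresis loop has a definite orientation
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  p <- study_probes()$sphere
  for (m in list(relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.02),
                 relaxation_model("springpot", E_alpha1 = 1000, alpha = 0.3))) {
    fc <- simulate_curve(m, h, p, n_steps = 300)
    d <- as.data.frame(fc)
    app <- d[d$phase == "approach", ]
    ret <- d[d$phase == "retract", ]
    f_app_at <- approx(app$indentation_m, app$force_N, xout = ret$indentation_m,
                       rule = 2)$y
    expect_true(all(ret$force_N <= f_app_at * (1 + 1e-9)), info = m$name)
  }
})

test_that("the error decreases under grid refinement", {
  m <- relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.02)
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  p <- study_probes()$sphere
  ref <- simulate_curve(m, h, p, n_steps = 3200)
  e_coarse <- curve_error(simulate_curve(m, h, p, n_steps = 200), ref)
  e_fine <- curve_error(simulate_curve(m, h, p, n_steps = 800), ref)
  expect_lt(e_fine, e_coarse / 2)
})

test_that("forces scale linearly in the modulus and as delta_max^n", {
  h1 <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  h2 <- indentation_history("triangular", delta_max = 200e-9, t_m = 0.05)
  p <- study_probes()$sphere
  m1 <- relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.02)
  m3 <- relaxation_model("sls", E0 = 3000, E_inf = 900, tau = 0.02)
  f1 <- simulate_curve(m1, h1, p, n_steps = 200)
  f3 <- simulate_curve(m3, h1, p, n_steps = 200)
  expect_equal(f3$force, 3 * f1$force, tolerance = 1e-10)
  expect_equal(f3$t_detach, f1$t_detach, tolerance = 1e-10)
  f2 <- simulate_curve(m1, h2, p, n_steps = 200)
  expect_equal(f2$force, 2^1.5 * f1$force, tolerance = 1e-10)
})

test_that("the arbitrary-grid reference integrator agrees with the solver", {
  m <- relaxation_model("fractional_sls", E0 = 1000, E_inf = 300,
                        alpha = 0.5, tau = 0.02)
  h <- indentation_history("sinusoidal", delta_max = 100e-9, t_m = 0.05)
  p <- study_probes()$sphere
  fc <- simulate_curve(m, h, p, n_steps = 800)
  tg <- seq(0.005, 0.05, by = 0.005)
  f_ref <- approach_force(m, h, p, seq(1e-5, 0.05, length.out = 2000))
  f_num <- approx(fc$t[fc$phase == "approach"],
                  fc$force[fc$phase == "approach"], xout = tg)$y
  f_ref_tg <- approx(seq(1e-5, 0.05, length.out = 2000), f_ref, xout = tg)$y
  expect_lt(max(abs(f_num - f_ref_tg)) / max(f_ref_tg), 1e-3)
})

test_that("a bottom-effect factor scales shallow forces as supplied", {
  m <- relaxation_model("spring", E = 1000)
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  p <- study_probes()$sphere
  base <- simulate_curve(m, h, p, n_steps = 200)
  boosted <- simulate_curve(m, h, p, n_steps = 200, f_bec = function(d) 2)
  app <- base$phase == "approach"
  expect_equal(boosted$force[app], 2 * base$force[app], tolerance = 1e-12)
})

test_that("solver input validation", {
  m <- relaxation_model("spring", E = 1000)
  h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
  p <- study_probes()$sphere
  expect_error(simulate_curve(m, h, p, n_steps = 10), "at least 100")
  expect_error(t1_function(m, h, c(0.02)), "retraction_times")
  expect_error(approach_force(m, h, p, c(0.02, 0.01)), "ascending")
})
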