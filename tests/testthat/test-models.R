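# relaxation_model(): construction, limits, characteristic times,
# parameter-boundary reductions and the time-averaged modulus.

catalogue <- function() list(
  spring = relaxation_model("spring", E = 1000),
  dashpot = relaxation_model("dashpot", eta = 10),
  kelvin_voigt = relaxation_model("kelvin_voigt", E_inf = 1000, eta = 10),
  maxwell = relaxation_model("maxwell", E0 = 1000, tau = 0.1),
  sls = relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.1),
  gen_maxwell = relaxation_model("gen_maxwell", E_s = c(700, 500),
                                 tau = c(0.01, 1), E_inf = 300),
  springpot = relaxation_model("springpot", E_alpha1 = 1000, alpha = 0.5),
  fractional_kv = relaxation_model("fractional_kv", E_inf = 300,
                                   E_alpha1 = 500, alpha = 0.6),
  springpot_spring_series = relaxation_model("springpot_spring_series",
                                             E0 = 1000, E_alpha1 = 500,
                                             alpha = 0.4),
  springpot_dashpot_parallel = relaxation_model("springpot_dashpot_parallel",
                                                E_alpha1 = 500, alpha = 0.4,
                                                eta = 10),
  springpot_dashpot_series = relaxation_model("springpot_dashpot_series",
                                              E_beta1 = 200, beta = 0.3,
                                              eta = 500),
  two_springpots_parallel = relaxation_model("two_springpots_parallel",
                                             E_alpha1 = 500, alpha = 0.7,
                                             E_beta1 = 200, beta = 0.2),
  two_springpots_series = relaxation_model("two_springpots_series",
                                           E_alpha1 = 500, alpha = 0.7,
                                           E_beta1 = 200, beta = 0.2),
  fractional_sls = relaxation_model("fractional_sls", E0 = 1000,
                                    E_inf = 300, alpha = 0.5, tau = 0.1),
  fractional_sls_dashpot = relaxation_model("fractional_sls_dashpot",
                                            E_beta1 = 1000, beta = 0.3,
                                            eta = 1000, E_inf = 300)
)

test_that("all catalogued models build and relax monotonically", {
  tg <- 10^seq(-3, 3, length.out = 60)
  for (m in catalogue()) {
    expect_s3_class(m, "relaxation_model")
    v <- eval_relaxation(m, tg)
    expect_true(all(is.finite(v)), info = m$name)
    expect_true(all(v >= 0), info = m$name)
    expect_true(all(diff(v) <= 1e-12 * v[1]), info = m$name)
  }
})

test_that("instantaneous and equilibrium limits are honored", {
  ms <- catalogue()
  expect_equal(eval_relaxation(ms$spring, c(1e-6, 1e6)), c(1000, 1000))
  expect_equal(ms$maxwell$E0, 1000)
  expect_equal(ms$maxwell$E_inf, 0)
  expect_equal(ms$sls$E0, 1000)
  expect_equal(ms$sls$E_inf, 300)
  expect_equal(eval_relaxation(ms$sls, 1e-9), 1000, tolerance = 1e-7)
  expect_equal(eval_relaxation(ms$sls, 1e4), 300, tolerance = 1e-7)
  expect_equal(ms$gen_maxwell$E0, 1500)
  expect_identical(ms$kelvin_voigt$E0, Inf)
  expect_identical(ms$dashpot$E0, Inf)
  expect_equal(ms$fractional_sls$E_inf, 300)
  # springpot value at the 1 s reference time equals its modulus scale
  expect_equal(eval_relaxation(ms$springpot, 1), 1000)
})

test_that("characteristic times follow the catalogued conventions", {
  expect_equal(relaxation_model("kelvin_voigt", E_inf = 1000,
                                eta = 10)$char_time[["tau_KV"]], 0.01)
  expect_equal(relaxation_model("maxwell", E0 = 1000,
                                eta = 10)$char_time[["tau_MW"]], 0.01)
  m <- relaxation_model("sls", E0 = 1000, E_inf = 300, eta = 70)
  expect_equal(m$char_time[["tau_rel"]], 0.1)
  expect_equal(m$char_time[["tau_creep"]], 1000 * 70 / (300 * 700))
  m <- relaxation_model("fractional_kv", E_inf = 300, E_alpha1 = 500,
                        alpha = 0.6)
  expect_equal(m$char_time[[1]], (500 / 300)^(1 / 0.6))
  m <- relaxation_model("two_springpots_parallel", E_alpha1 = 500,
                        alpha = 0.7, E_beta1 = 200, beta = 0.2)
  expect_equal(m$char_time[[1]], (500 / 200)^(1 / 0.5))
})

test_that("boundary exponents reduce to the simpler catalogued models", {
  tg <- 10^seq(-3, 3, length.out = 25)
  pairs <- list(
    list(relaxation_model("two_springpots_series", E_alpha1 = 500,
                          alpha = 1, E_beta1 = 200, beta = 0.3),
         relaxation_model("springpot_dashpot_series", E_beta1 = 200,
                          beta = 0.3, eta = 500)),
    list(relaxation_model("two_springpots_series", E_alpha1 = 500,
                          alpha = 0.6, E_beta1 = 200, beta = 0),
         relaxation_model("springpot_spring_series", E0 = 200,
                          E_alpha1 = 500, alpha = 0.6)),
    list(relaxation_model("fractional_sls_dashpot", E_beta1 = 700,
                          beta = 0, eta = 70, E_inf = 300),
         relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.1)),
    list(relaxation_model("fractional_sls", E0 = 1000, E_inf = 300,
                          alpha = 1, tau = 0.1),
         relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.1))
  )
  for (p in pairs) {
    a <- eval_relaxation(p[[1]], tg)
    b <- eval_relaxation(p[[2]], tg)
    expect_lt(max(abs(a - b) / b), 1e-10)
  }
})

test_that("time-averaged modulus: closed forms match adaptive quadrature", {
  ti <- c(0.013, 1, 170)
  for (m in catalogue()) {
    ex <- time_averaged_modulus(m, ti)
    qd <- time_averaged_modulus(m, ti, method = "quadrature")
    expect_lt(max(abs(ex - qd) / ex), 1e-9, label = m$name)
  }
})

test_that("time-averaged modulus closed forms for elementary models", {
  ti <- 4  # quarter cycle = 1 s
  expect_equal(time_averaged_modulus(relaxation_model("spring", E = 1000), ti),
               1000)
  expect_equal(
    time_averaged_modulus(relaxation_model("maxwell", E0 = 1000, tau = 1), ti),
    1000 * (1 - exp(-1)))
  expect_equal(
    time_averaged_modulus(relaxation_model("kelvin_voigt", E_inf = 1000,
                                           eta = 10), ti),
    1000 + 10 / 1)
  expect_equal(
    time_averaged_modulus(relaxation_model("springpot", E_alpha1 = 1000,
                                           alpha = 0.5), ti),
    1000 / 0.5)  # E1 * T4^(1-a)/(1-a) / T4 at T4 = 1
})

test_that("log-slope of the time average recovers power-law exponents", {
  sl <- log_slope_time_average(relaxation_model("springpot",
                                                E_alpha1 = 1000,
                                                alpha = 0.3), c(0.1, 1, 10))
  expect_equal(sl, rep(-0.3, 3), tolerance = 1e-9)
  expect_equal(
    log_slope_time_average(relaxation_model("spring", E = 1000), 1), 0,
    tolerance = 1e-9)
  expect_equal(
    log_slope_time_average(relaxation_model("dashpot", eta = 10), 1), -1,
    tolerance = 1e-9)
})

test_that("springpot rescaling converts a non-1s reference to the 1s scale", {
  # a springpot quoted as "E = 1000 Pa at 0.01 s" must evaluate to 1000 Pa
  # at 0.01 s once its modulus scale is converted to the 1 s convention
  E_at_ref <- 1000; a <- 0.4; tau_ref <- 0.01
  m <- relaxation_model("springpot",
                        E_alpha1 = rescale_springpot(E_at_ref, a, tau_ref),
                        alpha = a)
  expect_equal(eval_relaxation(m, tau_ref), E_at_ref, tolerance = 1e-12)
  expect_error(rescale_springpot(1000, 0.4, 0), "positive")
})

test_that("invalid parameters are rejected", {
  expect_error(relaxation_model("no_such_model", E = 1), "unknown model")
  expect_error(relaxation_model("spring"), "missing parameter")
  expect_error(relaxation_model("spring", E = -1), "positive")
  expect_error(relaxation_model("sls", E0 = 300, E_inf = 300, tau = 1),
               "below")
  expect_error(relaxation_model("springpot", E_alpha1 = 1, alpha = 0),
               "range")
  expect_error(relaxation_model("springpot", E_alpha1 = 1, alpha = 1.1),
               "range")
  expect_error(relaxation_model("gen_maxwell", E_s = c(1, -1), tau = c(1, 2)),
               "non-negative")
  expect_error(relaxation_model("gen_maxwell", E_s = 1, tau = c(1, 2)),
               "lengths")
})
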