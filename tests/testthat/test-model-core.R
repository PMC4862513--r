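test_that("infusion concentration is zero at start and for zero dose", {
  p <- typ_group("healthy")
  expect_identical(conc_iv_infusion(p, 100, 2, 0), 0)
  expect_identical(conc_iv_infusion(p, 0, 2, c(0, 1, 24)), c(0, 0, 0))
  expect_identical(conc_oral_weibull(p, 100, 0), 0)
  expect_identical(conc_oral_weibull(p, 0, c(0, 4, 24)), c(0, 0, 0))
})

test_that("invalid structural parameters are rejected", {
  expect_error(structural_params(cl = -1, vc = 5e4, q = 4e4, vp = 4e5),
               "positive")
  expect_error(structural_params(cl = 2000, vc = 5e4, q = 4e4, vp = 4e5,
                                 f1 = 1.2), "f1")
})

test_that("closed-form infusion kinetics match adaptive ODE integration", {
  times <- c(0.5, 1, 2, 2.5, 4, 8, 24, 48, 120, 240, 480)
  # typical healthy subject, tight agreement
  p <- typ_group("healthy")
  got <- conc_iv_infusion(p, 100, 2, times)
  ref <- ode_iv_oracle(p, 100, 2, times)
  expect_equal(got, ref, tolerance = 1e-8)
  # 100 random positive parameter sets, relative error < 1e-6
  worst <- 0
  for (p in random_params(100, seed = 42)) {
    got <- conc_iv_infusion(p, 100, 2, times)
    ref <- ode_iv_oracle(p, 100, 2, times, rtol = 1e-11)
    # relative error guarded against the oracle's own floor at
    # concentrations many orders below the peak
    worst <- max(worst, max(abs(got - ref) / (ref + 1e-6 * max(ref))))
  }
  expect_lt(worst, 1e-6)
})

test_that("oral Weibull solver matches an independent stiff-capable oracle", {
  times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 24, 48, 120, 240, 480)
  for (p in random_params(20, seed = 7)) {
    got <- conc_oral_weibull(p, 100, times)
    ref <- ode_oral_oracle(p, 100, times)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("Q -> 0 reduces both routes to one-compartment kinetics", {
  p1 <- structural_params(cl = 2540, vc = 51400, q = 1e-8, vp = 410000)
  k <- p1$cl / p1$vc
  r0 <- 100e6 / 2
  one_cpt <- function(t) {
    te <- pmin(t, 2)
    r0 / p1$cl * (1 - exp(-k * te)) * exp(-k * pmax(t - 2, 0))
  }
  times <- c(0.5, 1, 2, 6, 24, 96, 240)
  expect_equal(conc_iv_infusion(p1, 100, 2, times), one_cpt(times),
               tolerance = 1e-6)
})

test_that("AUC to infinity equals dose*F1/CL for both routes", {
  p <- typ_group("healthy")
  beta <- disposition_constants(p)$beta
  tmax <- 6000  # ~45 terminal half-lives; analytic tail below
  for (fun in list(function(t) conc_iv_infusion(p, 100, 2, t),
                   function(t) conc_oral_weibull(p, 100, t))) {
    auc <- stats::integrate(fun, 0, tmax, rel.tol = 1e-8,
                            subdivisions = 2000L)$value +
      fun(tmax) / beta
    expect_equal(auc, 100e6 * p$f1 / p$cl, tolerance = 0.005)
  }
})

test_that("late-time oral log-slope equals the smallest disposition eigenvalue", {
  p <- typ_group("healthy")
  beta <- disposition_constants(p)$beta
  tt <- seq(1500, 2000, by = 50)   # absorption long over; pure terminal phase
  slope <- -stats::coef(stats::lm(log(conc_oral_weibull(p, 100, tt)) ~ tt))[[2]]
  expect_equal(slope, beta, tolerance = 1e-4)
})

test_that("superposition is linear and a single event reduces to the single dose", {
  p <- typ_group("mild")
  times <- c(1, 6, 23.9, 30, 50, 100)
  reg1 <- regimen(100, "iv_infusion", duration = 2, n_doses = 1)
  expect_equal(superpose(p, reg1, times)$conc,
               conc_iv_infusion(p, 100, 2, times), tolerance = 1e-12)
  reg <- clinical_regimen(n_maintenance = 3)
  base <- superpose(p, reg, times)$conc
  reg2 <- reg
  reg2$amount <- 2 * reg2$amount
  expect_equal(superpose(p, reg2, times)$conc, 2 * base, tolerance = 1e-9)
  # oral events superpose too
  rego <- regimen(100, "oral", start = 0, interval = 12, n_doses = 2)
  expect_equal(superpose(p, rego, 20)$conc,
               conc_oral_weibull(p, 100, 20) + conc_oral_weibull(p, 100, 8),
               tolerance = 1e-8)
})

test_that("repeated q24h dosing converges to the steady-state trough operator", {
  p <- typ_group("healthy")
  ss <- steady_state_trough(p, 200, "iv_infusion", 2, 24)
  reg <- regimen(200, "iv_infusion", duration = 2, interval = 24,
                 n_doses = 60)
  tr60 <- superpose(p, reg, 60 * 24 - 1e-9)$conc
  expect_equal(tr60, ss, tolerance = 0.005)
})

test_that("one-compartment bolus limit of the trough matches the textbook form", {
  p <- structural_params(cl = 2000, vc = 50000, q = 1e-9, vp = 4e5)
  k <- p$cl / p$vc
  tau <- 24
  expected <- (200e6 / p$vc) * exp(-k * tau) / (1 - exp(-k * tau))
  got <- steady_state_trough(p, 200, "iv_infusion", duration = 1e-4,
                             interval = tau)
  expect_equal(got, expected, tolerance = 1e-3)
})

test_that("oral steady-state trough agrees with the iv operator and detects non-convergence", {
  p <- typ_group("moderate")
  iv <- steady_state_trough(p, 200, "iv_infusion", 2, 24)
  oral <- steady_state_trough(p, 200, "oral", interval = 24)
  expect_equal(oral, iv, tolerance = 0.05)
  expect_error(steady_state_trough(p, 200, "oral", interval = 24,
                                   max_intervals = 3),
               "steady state not reached")
})

test_that("trough washes out as the interval grows without bound", {
  p <- typ_group("healthy")
  expect_lt(steady_state_trough(p, 200, "iv_infusion", 2, 1e5), 1e-6)
})

test_that("typical terminal half-lives exceed 100 h (steady state takes days)", {
  for (g in c("healthy", "mild", "moderate")) {
    beta <- disposition_constants(typ_group(g))$beta
    expect_gt(log(2) / beta, 100)
  }
})

test_that("steady-state interval profile brackets the trough and matches mass balance", {
  p <- typ_group("healthy")
  prof <- steady_state_profile(p, 200, duration = 2, interval = 24,
                               times = seq(0, 24, length.out = 2401))
  trough <- steady_state_trough(p, 200, "iv_infusion", 2, 24)
  cavg <- mean(prof$conc[-1] + prof$conc[-nrow(prof)]) / 2
  expect_equal(cavg, 200e6 / (p$cl * 24), tolerance = 0.01)
  expect_lt(trough, cavg)
  expect_gt(max(prof$conc), cavg)
  expect_equal(prof$conc[nrow(prof)], trough, tolerance = 1e-8)
})
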