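# Shared fixtures and independent numerical oracles for the test suite.

# typical parameters for one hepatic group at a given BMI
typ_group <- function(group, bmi = 27, theta = theta_reference()) {
  typical_params(data.frame(hepatic_group = group, bmi = bmi), theta)
}

# post-dose sampling schedule of the hepatic studies (h)
study_times <- function() {
  c(0.5, 1, 2, 3, 4, 6, 8, 10, 24, 48, 72, 96, 120, 144, 168,
    216, 288, 360, 432, 480)
}

# a parameter table with no between-subject variability
theta_novar <- function(sigma = 1e-9) {
  th <- theta_reference()
  theta_table(
    cl_healthy = th$cl[["healthy"]], cl_mild = th$cl[["mild"]],
    cl_moderate = th$cl[["moderate"]], vc = th$vc,
    q_healthy = th$q[["healthy"]], q_mild = th$q[["mild"]],
    q_moderate = th$q[["moderate"]], vp = th$vp, ra = th$ra,
    gam1 = th$gam1, kamax = th$kamax, bmi_vp = th$bmi_vp, f1 = th$f1,
    omega = c(cl = 0, vc = 0, q = 0, vp = 0, ra = 0, gam1 = 0, kamax = 0),
    sigma = sigma, bmi_ref = th$bmi_ref
  )
}

# Independent ODE oracle for the iv infusion (deSolve::lsoda, integrated
# piecewise so the input discontinuity at end of infusion is exact).
ode_iv_oracle <- function(p, dose, duration, times, rtol = 1e-10) {
  p <- as.list(p)
  k10 <- p$cl / p$vc; k12 <- p$q / p$vc; k21 <- p$q / p$vp
  rate <- dose * 1e6 / duration
  f <- function(t, y, parms) {
    list(c(parms - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  atol <- 1e-14 * dose * 1e6
  times <- as.numeric(times)
  t1 <- sort(unique(c(0, times[times <= duration], duration)))
  out1 <- deSolve::lsoda(c(0, 0), t1, f, parms = rate, rtol = rtol,
                         atol = atol)
  y_end <- out1[nrow(out1), 2:3]
  t2 <- sort(unique(c(duration, times[times > duration])))
  out2 <- if (length(t2) > 1) {
    deSolve::lsoda(y_end, t2, f, parms = 0, rtol = rtol, atol = atol)
  } else NULL
  conc_at <- function(t) {
    if (t <= duration) out1[match(t, t1), 2] / p$vc
    else out2[match(t, t2), 2] / p$vc
  }
  vapply(times, conc_at, numeric(1))
}

# Independent ODE oracle for the oral Weibull absorption route.
ode_oral_oracle <- function(p, dose, times, rtol = 1e-10) {
  p <- as.list(p)
  k10 <- p$cl / p$vc; k12 <- p$q / p$vc; k21 <- p$q / p$vp
  f <- function(t, y, parms) {
    ka <- if (t > 0) p$kamax * (1 - exp(-(p$ra * t)^p$gam1)) else 0
    list(c(-ka * y[1],
           ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  tt <- sort(unique(c(0, as.numeric(times))))
  out <- deSolve::lsoda(c(dose * 1e6 * p$f1, 0, 0), tt, f, parms = NULL,
                        rtol = rtol, atol = 1e-10 * dose * 1e6)
  out[match(as.numeric(times), tt), 3] / p$vc
}

# random plausible positive parameter sets for property-style checks
random_params <- function(n, seed = 1) {
  withr::local_seed(seed)
  lapply(seq_len(n), function(i) {
    structural_params(
      cl = stats::rlnorm(1, log(2000), 0.8),
      vc = stats::rlnorm(1, log(50000), 0.8),
      q = stats::rlnorm(1, log(40000), 0.8),
      vp = stats::rlnorm(1, log(400000), 0.8),
      ra = stats::rlnorm(1, log(0.65), 0.4),
      gam1 = stats::rlnorm(1, log(4.5), 0.3),
      kamax = stats::rlnorm(1, log(0.86), 0.4)
    )
  })
}

# simulate one iv-arm subject's observations from known parameters
sim_iv_subject <- function(p, dose = 100, duration = 2, sigma = 0,
                           times = study_times(), seed = 1) {
  conc <- conc_iv_infusion(p, dose, duration, times)
  if (sigma > 0) {
    withr::local_seed(seed)
    conc <- exp(log(conc) + stats::rnorm(length(conc), 0, sigma))
  }
  list(
    events = tibble::tibble(time = 0, amount = dose, route = "iv_infusion",
                            duration = duration),
    obs = tibble::tibble(time = times, conc = conc)
  )
}

# build a minimal iv-only NONMEM-style dataset from a vector of subjects
make_iv_dataset <- function(cl, group, sigma, seed, vc = 51400, q = 33678,
                            vp = 410000, dose = 100, duration = 2,
                            times = study_times()) {
  withr::local_seed(seed)
  purrr::map_dfr(seq_along(cl), function(i) {
    p <- structural_params(cl = cl[i], vc = vc, q = q, vp = vp)
    conc <- conc_iv_infusion(p, dose, duration, times)
    dv <- exp(log(conc) + stats::rnorm(length(times), 0, sigma))
    hep <- c(healthy = 0L, mild = 1L, moderate = 2L)[[group[i]]]
    base <- tibble::tibble(ID = i, HEP = hep, BMI = 27, AGE = 50, SEX = 1L,
                           WT = 78, HT = 171, SMOK = 0L, BILI = 8, ALB = 4.5,
                           PT = 1, ROUTE = 1L, STUDY = 1L)
    dplyr::bind_rows(
      dplyr::mutate(base, TIME = 0, AMT = dose, RATE = dose / duration,
                    EVID = 1L, MDV = 1L, CMT = 2L, DV = 0),
      dplyr::bind_cols(base[rep(1, length(times)), ],
                       tibble::tibble(TIME = times, AMT = 0, RATE = 0,
                                      EVID = 0L, MDV = 0L, CMT = 2L,
                                      DV = dv))
    )
  })
}
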