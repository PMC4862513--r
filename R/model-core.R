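#' Disposition rate constants and eigenvalues of the two-compartment model
#'
#' Converts clearance-style parameters to micro rate constants
#' (`k10 = cl/vc`, `k12 = q/vc`, `k21 = q/vp`) and returns the two
#' disposition eigenvalues `alpha > beta` (1/h) together with the
#' bolus-response coefficients `ca`, `cb` such that a unit bolus gives
#' central concentration `(D/vc) * (ca*exp(-alpha*t) + cb*exp(-beta*t))`.
#'
#' @param p A [structural_params()], named list or one-row data frame.
#' @return A list with `k10`, `k12`, `k21`, `alpha`, `beta`, `ca`, `cb`.
#' @examples
#' d <- disposition_constants(typical_params(
#'   data.frame(hepatic_group = "healthy", bmi = 27)))
#' log(2) / d$beta  # terminal half-life, h
#' @export
disposition_constants <- function(p) {
  p <- as_structural_params(p)
  disp_vec(p$cl, p$vc, p$q, p$vp)
}

# vectorized over subjects
disp_vec <- function(cl, vc, q, vp) {
  k10 <- cl / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta,
       ca = (alpha - k21) / (alpha - beta), cb = (k21 - beta) / (alpha - beta))
}

#' Concentration after a zero-order intravenous infusion
#'
#' Exact bi-exponential closed-form solution for a constant-rate infusion of
#' duration `duration` into the central compartment of the two-compartment
#' model with first-order elimination.
#'
#' @param p A [structural_params()], named list or one-row data frame.
#' @param dose Dose, mg.
#' @param duration Infusion duration, h (> 0).
#' @param times Times after infusion start, h (>= 0); may be unsorted.
#' @return Concentrations in ng/ml, one per element of `times`.
#' @examples
#' p <- typical_params(data.frame(hepatic_group = "healthy", bmi = 27))
#' conc_iv_infusion(p, dose = 100, duration = 2, times = c(0, 1, 2, 24, 480))
#' @export
conc_iv_infusion <- function(p, dose, duration, times) {
  p <- as_structural_params(p)
  stopifnot(dose >= 0, duration > 0, all(times >= 0))
  if (dose == 0) return(numeric(length(times)))
  d <- disp_vec(p$cl, p$vc, p$q, p$vp)
  r0 <- dose * 1e6 / duration  # ng/h
  term <- function(lam, coef) {
    during <- coef / lam * (1 - exp(-lam * pmin(times, duration)))
    decay <- exp(-lam * pmax(times - duration, 0))
    during * decay
  }
  (r0 / p$vc) * (term(d$alpha, d$ca) + term(d$beta, d$cb))
}

#' Concentration after an oral dose with Weibull-type absorption
#'
#' Numerically integrates the depot/central/peripheral system in which the
#' absorption rate constant rises sigmoidally with time,
#' `ka(t) = kamax * (1 - exp(-(ra*t)^gam1))`, saturating at `kamax`. This
#' time-dependent first-order form is the package's reading of the
#' three-parameter Weibull input (`ra`, `gam1`, `kamax`); see the methods
#' vignette. Integration uses an adaptive embedded Runge-Kutta method with
#' relative tolerance well below 1e-8.
#'
#' @inheritParams conc_iv_infusion
#' @param rtol Relative integration tolerance.
#' @return Concentrations in ng/ml, one per element of `times`.
#' @examples
#' p <- typical_params(data.frame(hepatic_group = "healthy", bmi = 27))
#' conc_oral_weibull(p, dose = 100, times = c(0, 1, 2, 4, 8, 24))
#' @export
conc_oral_weibull <- function(p, dose, times, rtol = 1e-10) {
  p <- as_structural_params(p)
  stopifnot(dose >= 0, all(times >= 0))
  if (dose == 0) return(numeric(length(times)))
  ord <- order(times)
  res <- oral_weibull_central(as.numeric(times[ord]), dose * 1e6,
                              p$cl, p$vc, p$q, p$vp,
                              p$ra, p$gam1, p$kamax, p$f1, rtol)
  out <- numeric(length(times))
  out[ord] <- res
  out
}

#' Build a dosing regimen
#'
#' A regimen is an ordered event table (one row per administration) with
#' columns `time` (h), `amount` (mg), `route` (`"iv_infusion"` or `"oral"`)
#' and `duration` (h; `NA` for oral doses). The repeating maintenance
#' pattern is stored as an attribute so steady-state operators can work
#' from the maintenance event alone.
#'
#' @param amount Dose amount, mg.
#' @param route `"iv_infusion"` or `"oral"`.
#' @param duration Infusion duration, h (ignored for oral).
#' @param start Time of the first dose, h.
#' @param interval Dosing interval, h.
#' @param n_doses Number of doses.
#' @param label Free-text label.
#' @return A tibble of dose events with class `pk_regimen`.
#' @export
regimen <- function(amount, route = c("iv_infusion", "oral"), duration = 2,
                    start = 0, interval = 24, n_doses = 1, label = "") {
  route <- match.arg(route)
  stopifnot(amount >= 0, start >= 0, interval > 0, n_doses >= 1)
  if (route == "iv_infusion" && duration <= 0) {
    stop("infusion events need `duration` > 0", call. = FALSE)
  }
  dur <- if (route == "iv_infusion") duration else NA_real_
  ev <- tibble::tibble(
    time = start + interval * (seq_len(n_doses) - 1),
    amount = amount,
    route = route,
    duration = dur
  )
  new_regimen(ev, label = label,
              maintenance = list(amount = amount, route = route,
                                 duration = duration, interval = interval))
}

new_regimen <- function(events, label = "", maintenance = NULL) {
  out <- tibble::as_tibble(events[order(events$time), ])
  attr(out, "label") <- label
  attr(out, "maintenance") <- maintenance
  class(out) <- c("pk_regimen", class(tibble::tibble()))
  out
}

#' The clinical loading/maintenance regimen
#'
#' 200 mg every 8 h for 2 days (6 doses) followed by 200 mg once daily --
#' the labelled dosing of isavuconazole. Doses are modelled as 2-h
#' intravenous infusions by default; with complete oral bioavailability and
#' a multi-day terminal half-life, steady-state troughs are essentially
#' route-independent.
#'
#' @param amount Dose amount, mg.
#' @param route `"iv_infusion"` or `"oral"`.
#' @param duration Infusion duration, h.
#' @param n_maintenance Number of once-daily maintenance doses to lay out.
#' @return A `pk_regimen` event table (see [regimen()]).
#' @export
clinical_regimen <- function(amount = 200, route = c("iv_infusion", "oral"),
                             duration = 2, n_maintenance = 28) {
  route <- match.arg(route)
  dur <- if (route == "iv_infusion") duration else NA_real_
  load <- tibble::tibble(
    time = seq(0, by = 8, length.out = 6), amount = amount, route = route,
    duration = dur
  )
  maint <- tibble::tibble(
    time = 48 + 24 * (seq_len(n_maintenance) - 1), amount = amount,
    route = route, duration = dur
  )
  new_regimen(dplyr::bind_rows(load, maint), label = "clinical",
              maintenance = list(amount = amount, route = route,
                                 duration = duration, interval = 24))
}

maintenance_info <- function(reg) {
  m <- attr(reg, "maintenance")
  if (is.null(m)) {
    # infer from the trailing events: last interval and last event
    ev <- reg[order(reg$time), ]
    n <- nrow(ev)
    if (n < 2) {
      m <- list(amount = ev$amount[n], route = ev$route[n],
                duration = ev$duration[n], interval = 24)
    } else {
      m <- list(amount = ev$amount[n], route = ev$route[n],
                duration = ev$duration[n],
                interval = ev$time[n] - ev$time[n - 1])
    }
  }
  m
}

#' Superpose single-dose solutions over a regimen
#'
#' The model is linear, so the concentration at time `t` is the sum of
#' single-dose contributions from every event administered at or before
#' `t`. Intravenous contributions use the closed-form solution; oral
#' contributions are integrated numerically once per event.
#'
#' @param p A [structural_params()], named list or one-row data frame.
#' @param reg A [regimen()] / [clinical_regimen()] event table, or any data
#'   frame with columns `time`, `amount`, `route`, `duration`.
#' @param times Evaluation times, h (>= 0).
#' @return A tibble with columns `time` (h) and `conc` (ng/ml).
#' @export
superpose <- function(p, reg, times) {
  p <- as_structural_params(p)
  stopifnot(all(times >= 0))
  conc <- numeric(length(times))
  for (i in seq_len(nrow(reg))) {
    amt <- reg$amount[i]
    if (amt <= 0) next
    off <- times - reg$time[i]
    active <- off > 0
    if (!any(active)) next
    ci <- if (reg$route[i] == "iv_infusion") {
      conc_iv_infusion(p, amt, reg$duration[i], off[active])
    } else {
      conc_oral_weibull(p, amt, off[active])
    }
    conc[active] <- conc[active] + ci
  }
  tibble::tibble(time = as.numeric(times), conc = conc)
}

#' Steady-state trough concentration under repeated dosing
#'
#' Trough at the end of the dosing interval once accumulation is complete.
#' For intravenous infusions each exponential term of the single-dose
#' solution is summed in closed form with the geometric accumulation factor
#' `1/(1 - exp(-lambda*tau))`. For oral doses the single-dose profile is
#' evaluated at multiples of the interval and doses are stacked until the
#' trough changes by less than 0.1% between successive intervals.
#'
#' @param p A [structural_params()], named list or one-row data frame.
#' @param amount Maintenance dose, mg.
#' @param route `"iv_infusion"` or `"oral"`.
#' @param duration Infusion duration, h (infusions only).
#' @param interval Dosing interval tau, h; must exceed `duration`.
#' @param max_intervals Give up (with an error) after this many stacked
#'   intervals without oral convergence.
#' @return Trough concentration, ng/ml.
#' @examples
#' p <- typical_params(data.frame(hepatic_group = "moderate", bmi = 27))
#' steady_state_trough(p, amount = 200, route = "iv_infusion",
#'                     duration = 2, interval = 24)
#' @export
steady_state_trough <- function(p, amount, route = c("iv_infusion", "oral"),
                                duration = 2, interval = 24,
                                max_intervals = 200) {
  route <- match.arg(route)
  p <- as_structural_params(p)
  stopifnot(amount >= 0, interval > 0)
  if (amount == 0) return(0)
  if (route == "iv_infusion") {
    if (interval <= duration) {
      stop("`interval` must exceed the infusion `duration`", call. = FALSE)
    }
    d <- disp_vec(p$cl, p$vc, p$q, p$vp)
    r0 <- amount * 1e6 / duration
    lam <- c(d$alpha, d$beta)
    coef <- c(d$ca, d$cb)
    # B*exp(-lam*tau) written overflow-safe as exp(-lam*(tau-T)) - exp(-lam*tau)
    num <- (exp(-lam * (interval - duration)) - exp(-lam * interval))
    sum((r0 / p$vc) * coef / lam * num / (1 - exp(-lam * interval)))
  } else {
    ages <- interval * seq_len(max_intervals)
    c1 <- conc_oral_weibull(p, amount, ages)
    tr <- cumsum(c1)
    rel <- c1 / pmax(tr, .Machine$double.xmin)
    k <- which(rel < 0.001)
    k <- k[k > 1][1]
    if (is.na(k)) {
      stop("steady state not reached within ", max_intervals,
           " intervals (oral accumulation)", call. = FALSE)
    }
    tr[k]
  }
}

# vectorized iv steady-state trough across subjects (internal fast path)
ss_trough_iv_vec <- function(cl, vc, q, vp, amount, duration, interval) {
  d <- disp_vec(cl, vc, q, vp)
  r0 <- amount * 1e6 / duration
  term <- function(lam, coef) {
    (r0 / vc) * coef / lam *
      (exp(-lam * (interval - duration)) - exp(-lam * interval)) /
      (1 - exp(-lam * interval))
  }
  term(d$alpha, d$ca) + term(d$beta, d$cb)
}

#' Intravenous concentration profile within a steady-state dosing interval
#'
#' Closed-form concentration at times `0 <= t <= interval` after the start
#' of a maintenance infusion at steady state: the single-dose contribution
#' plus the geometrically-summed tail of all earlier doses.
#'
#' @inheritParams steady_state_trough
#' @param times Times within the interval, h, in `[0, interval]`.
#' @return A tibble with columns `time` and `conc` (ng/ml).
#' @export
steady_state_profile <- function(p, amount, duration = 2, interval = 24,
                                 times = seq(0, interval, length.out = 241)) {
  p <- as_structural_params(p)
  stopifnot(all(times >= 0), all(times <= interval), interval > duration)
  d <- disp_vec(p$cl, p$vc, p$q, p$vp)
  r0 <- amount * 1e6 / duration
  lam <- c(d$alpha, d$beta)
  coef <- c(d$ca, d$cb)
  tail_term <- vapply(times, function(t) {
    sum((r0 / p$vc) * coef / lam *
          (exp(-lam * (t - duration + interval)) - exp(-lam * (t + interval))) /
          (1 - exp(-lam * interval)))
  }, numeric(1))
  tibble::tibble(
    time = as.numeric(times),
    conc = conc_iv_infusion(p, amount, duration, times) + tail_term
  )
}
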