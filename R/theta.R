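#' Population parameter table for the hepatic-impairment covariate model
#'
#' A `theta_table` bundles the fixed effects of the final covariate model
#' (typical clearance and intercompartmental clearance per hepatic-function
#' group, shared volumes and Weibull absorption constants, and the BMI slope
#' on peripheral volume), the log-scale between-subject standard deviations
#' (`omega`), and the additive log-scale residual standard deviation
#' (`sigma`).
#'
#' Units are internal-canonical: clearances in ml/h, volumes in ml, rate
#' constants in 1/h. `bmi_ref` is the BMI (kg/m^2) at which the peripheral
#' volume equals `vp`; the published model centres the linear BMI term at 27.
#'
#' @param cl_healthy,cl_mild,cl_moderate Typical clearance per group, ml/h.
#' @param vc Central volume of distribution, ml.
#' @param q_healthy,q_mild,q_moderate Typical intercompartmental clearance
#'   per group, ml/h.
#' @param vp Peripheral volume of distribution at the reference BMI, ml.
#' @param ra Weibull absorption rate parameter, 1/h.
#' @param gam1 Weibull absorption shape, dimensionless.
#' @param kamax Maximal absorption rate constant, 1/h.
#' @param bmi_vp Linear BMI slope on peripheral volume, per kg/m^2 (any sign).
#' @param f1 Oral bioavailability fraction, in (0, 1].
#' @param omega Named numeric vector of log-scale between-subject SDs for
#'   `cl`, `vc`, `q`, `vp`, `ra`, `gam1`, `kamax` (all >= 0).
#' @param sigma Residual SD, additive on the log-concentration scale (> 0).
#' @param bmi_ref Reference BMI for the peripheral-volume covariate, kg/m^2.
#' @return An object of class `theta_table`.
#' @seealso [theta_reference()] for the published reference values,
#'   [typical_params()] to evaluate the covariate model.
#' @export
theta_table <- function(cl_healthy, cl_mild, cl_moderate,
                        vc,
                        q_healthy, q_mild, q_moderate,
                        vp, ra, gam1, kamax, bmi_vp,
                        f1 = 1,
                        omega = c(cl = 0, vc = 0, q = 0, vp = 0,
                                  ra = 0, gam1 = 0, kamax = 0),
                        sigma = 1e-6,
                        bmi_ref = 27) {
  th <- list(
    cl = c(healthy = cl_healthy, mild = cl_mild, moderate = cl_moderate),
    q  = c(healthy = q_healthy,  mild = q_mild,  moderate = q_moderate),
    vc = vc, vp = vp, ra = ra, gam1 = gam1, kamax = kamax,
    bmi_vp = bmi_vp, f1 = f1,
    omega = omega, sigma = sigma, bmi_ref = bmi_ref
  )
  pos <- c(th$cl, th$q, vc = vc, vp = vp, ra = ra, gam1 = gam1, kamax = kamax)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all structural fixed effects must be strictly positive", call. = FALSE)
  }
  if (f1 <= 0 || f1 > 1) stop("`f1` must be in (0, 1]", call. = FALSE)
  need <- c("cl", "vc", "q", "vp", "ra", "gam1", "kamax")
  if (!all(need %in% names(omega))) {
    stop("`omega` must be named with: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(omega < 0)) stop("`omega` entries must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  th$omega <- omega[need]
  structure(th, class = "theta_table")
}

#' Published reference parameter table
#'
#' The final covariate-model estimates for isavuconazole in healthy subjects
#' and subjects with mild or moderate hepatic impairment: group-specific
#' clearance and intercompartmental clearance, shared central/peripheral
#' volumes, Weibull absorption constants, a linear BMI effect on peripheral
#' volume, log-normal between-subject variability on all seven structural
#' parameters, and additive residual error on the log scale.
#'
#' Reported percent "variability" values are interpreted as 100 times the
#' log-scale SD (e.g. 43.47 -> omega_cl = 0.4347); the residual error 17.88
#' likewise as sigma = 0.1788 on the log scale. The peripheral volume is
#' 410,000 ml (its bootstrap interval brackets that value).
#'
#' @return A [theta_table()] with the reference estimates.
#' @examples
#' th <- theta_reference()
#' th$cl[["healthy"]]  # 2540 ml/h
#' @export
theta_reference <- function() {
  theta_table(
    cl_healthy = 2540, cl_mild = 1550, cl_moderate = 1326,
    vc = 51400,
    q_healthy = 33678, q_mild = 38800, q_moderate = 63554,
    vp = 410000, ra = 0.653, gam1 = 4.57, kamax = 0.86,
    bmi_vp = 0.058, f1 = 1,
    omega = c(cl = 0.4347, vc = 0.2123, q = 0.3646, vp = 0.2705,
              ra = 0.3255, gam1 = 0.3807, kamax = 0.3178),
    sigma = 0.1788,
    bmi_ref = 27
  )
}

#' @export
print.theta_table <- function(x, ...) {
  cat("<theta_table>\n")
  cat(sprintf("  CL (ml/h): healthy %g, mild %g, moderate %g\n",
              x$cl[["healthy"]], x$cl[["mild"]], x$cl[["moderate"]]))
  cat(sprintf("  Q  (ml/h): healthy %g, mild %g, moderate %g\n",
              x$q[["healthy"]], x$q[["mild"]], x$q[["moderate"]]))
  cat(sprintf("  Vc %g ml, Vp %g ml (BMI slope %g per kg/m^2 about %g)\n",
              x$vc, x$vp, x$bmi_vp, x$bmi_ref))
  cat(sprintf("  absorption: RA %g 1/h, GAM1 %g, KAMAX %g 1/h, F1 %g\n",
              x$ra, x$gam1, x$kamax, x$f1))
  cat(sprintf("  omega (log-SD): %s\n",
              paste(sprintf("%s %.3f", names(x$omega), x$omega), collapse = ", ")))
  cat(sprintf("  sigma (log-SD): %.4f\n", x$sigma))
  invisible(x)
}

#' Tidy a parameter table into one row per parameter
#'
#' @param x A [theta_table()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `group`, `estimate`, `units`,
#'   and `type` (`"fixed"`, `"omega"` or `"sigma"`).
#' @exportS3Method generics::tidy
tidy.theta_table <- function(x, ...) {
  fixed <- tibble::tibble(
    parameter = c(rep("cl", 3), rep("q", 3),
                  "vc", "vp", "ra", "gam1", "kamax", "bmi_vp", "f1"),
    group = c(names(x$cl), names(x$q), rep(NA_character_, 7)),
    estimate = c(unname(x$cl), unname(x$q), x$vc, x$vp, x$ra, x$gam1,
                 x$kamax, x$bmi_vp, x$f1),
    units = c(rep("ml/h", 6), "ml", "ml", "1/h", "", "1/h", "per kg/m^2", ""),
    type = "fixed"
  )
  om <- tibble::tibble(
    parameter = names(x$omega), group = NA_character_,
    estimate = unname(x$omega), units = "log-SD", type = "omega"
  )
  sg <- tibble::tibble(parameter = "sigma", group = NA_character_,
                       estimate = x$sigma, units = "log-SD", type = "sigma")
  dplyr::bind_rows(fixed, om, sg)
}

#' Read or write a parameter table as a flat YAML config
#'
#' The on-disk format is a flat mapping with keys `CL_HEALTHY`, `CL_MILD`,
#' `CL_MODERATE`, `VC`, `Q_HEALTHY`, `Q_MILD`, `Q_MODERATE`, `VP`, `RA`,
#' `GAM1`, `KAMAX`, `BMI_VP`, `F1`, `BMI_REF`, `SIGMA` and `OMEGA_<PARAM>`
#' entries, in the canonical units (ml, ml/h, 1/h, log-scale SDs). A copy of
#' the reference table ships with the package
#' (`system.file("extdata", "theta_reference.yaml", package = "isavupk")`).
#'
#' @param path File path.
#' @return `read_theta()` returns a [theta_table()]; `write_theta()` returns
#'   `path` invisibly.
#' @export
read_theta <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(k) {
    if (is.null(y[[k]])) stop("missing key in theta config: ", k, call. = FALSE)
    as.numeric(y[[k]])
  }
  om <- c(cl = g("OMEGA_CL"), vc = g("OMEGA_VC"), q = g("OMEGA_Q"),
          vp = g("OMEGA_VP"), ra = g("OMEGA_RA"), gam1 = g("OMEGA_GAM1"),
          kamax = g("OMEGA_KAMAX"))
  theta_table(
    cl_healthy = g("CL_HEALTHY"), cl_mild = g("CL_MILD"),
    cl_moderate = g("CL_MODERATE"), vc = g("VC"),
    q_healthy = g("Q_HEALTHY"), q_mild = g("Q_MILD"),
    q_moderate = g("Q_MODERATE"), vp = g("VP"), ra = g("RA"),
    gam1 = g("GAM1"), kamax = g("KAMAX"), bmi_vp = g("BMI_VP"),
    f1 = g("F1"), omega = om, sigma = g("SIGMA"), bmi_ref = g("BMI_REF")
  )
}

#' @rdname read_theta
#' @param theta A [theta_table()].
#' @export
write_theta <- function(theta, path) {
  stopifnot(inherits(theta, "theta_table"))
  y <- list(
    CL_HEALTHY = theta$cl[["healthy"]], CL_MILD = theta$cl[["mild"]],
    CL_MODERATE = theta$cl[["moderate"]], VC = theta$vc,
    Q_HEALTHY = theta$q[["healthy"]], Q_MILD = theta$q[["mild"]],
    Q_MODERATE = theta$q[["moderate"]], VP = theta$vp, RA = theta$ra,
    GAM1 = theta$gam1, KAMAX = theta$kamax, BMI_VP = theta$bmi_vp,
    F1 = theta$f1, BMI_REF = theta$bmi_ref, SIGMA = theta$sigma,
    OMEGA_CL = theta$omega[["cl"]], OMEGA_VC = theta$omega[["vc"]],
    OMEGA_Q = theta$omega[["q"]], OMEGA_VP = theta$omega[["vp"]],
    OMEGA_RA = theta$omega[["ra"]], OMEGA_GAM1 = theta$omega[["gam1"]],
    OMEGA_KAMAX = theta$omega[["kamax"]]
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
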