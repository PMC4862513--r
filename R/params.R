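#' Single-subject structural parameter set
#'
#' Disposition and absorption constants for one subject of the
#' two-compartment model with Weibull oral absorption: clearance `cl` and
#' central volume `vc`, intercompartmental clearance `q` and peripheral
#' volume `vp`, Weibull rate `ra` and shape `gam1`, maximal absorption rate
#' constant `kamax`, and oral bioavailability `f1`.
#'
#' @param cl Clearance, ml/h.
#' @param vc Central volume, ml.
#' @param q Intercompartmental clearance, ml/h.
#' @param vp Peripheral volume, ml.
#' @param ra Weibull rate parameter, 1/h.
#' @param gam1 Weibull shape, dimensionless.
#' @param kamax Maximal absorption rate constant, 1/h.
#' @param f1 Oral bioavailability fraction, in (0, 1].
#' @return An object of class `structural_params` (a named list).
#' @examples
#' p <- structural_params(cl = 2540, vc = 51400, q = 33678, vp = 410000,
#'                        ra = 0.653, gam1 = 4.57, kamax = 0.86)
#' @export
structural_params <- function(cl, vc, q, vp, ra = 0.653, gam1 = 4.57,
                              kamax = 0.86, f1 = 1) {
  p <- list(cl = cl, vc = vc, q = q, vp = vp, ra = ra, gam1 = gam1,
            kamax = kamax, f1 = f1)
  validate_structural_params(p)
  structure(p, class = "structural_params")
}

validate_structural_params <- function(p) {
  num <- unlist(p[c("cl", "vc", "q", "vp", "ra", "gam1", "kamax", "f1")])
  if (length(num) != 8 || any(!is.finite(num))) {
    stop("structural parameters must be finite numbers (cl, vc, q, vp, ra, gam1, kamax, f1)",
         call. = FALSE)
  }
  if (any(num <= 0)) {
    stop("invalid parameter: all structural parameters must be strictly positive",
         call. = FALSE)
  }
  if (p$f1 > 1) stop("invalid parameter: f1 must be in (0, 1]", call. = FALSE)
  invisible(p)
}

# Coerce a structural_params object, named list, or one-row data frame.
as_structural_params <- function(p) {
  if (inherits(p, "structural_params")) return(p)
  if (is.data.frame(p)) {
    if (nrow(p) != 1) stop("expected a single-subject (one-row) parameter set", call. = FALSE)
    p <- as.list(p)
  }
  need <- c("cl", "vc", "q", "vp")
  if (!all(need %in% names(p))) {
    stop("parameter set must contain at least: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structural_params(cl = p$cl, vc = p$vc, q = p$q, vp = p$vp,
                    ra = p$ra %||% 0.653, gam1 = p$gam1 %||% 4.57,
                    kamax = p$kamax %||% 0.86, f1 = p$f1 %||% 1)
}

#' @export
print.structural_params <- function(x, ...) {
  cat("<structural_params>\n")
  cat(sprintf("  cl %g ml/h, vc %g ml, q %g ml/h, vp %g ml\n",
              x$cl, x$vc, x$q, x$vp))
  cat(sprintf("  ra %g 1/h, gam1 %g, kamax %g 1/h, f1 %g\n",
              x$ra, x$gam1, x$kamax, x$f1))
  invisible(x)
}

#' Evaluate the covariate model at its typical values
#'
#' Maps population fixed effects plus subject covariates to individual
#' *typical* structural parameters (all random effects at zero): clearance
#' and intercompartmental clearance are selected by hepatic-function group,
#' the peripheral volume is scaled linearly in BMI about the reference BMI
#' (`vp * (1 + bmi_vp * (BMI - bmi_ref))`), and all remaining parameters are
#' taken directly from the table.
#'
#' @param covariates A data frame with one row per subject and columns
#'   `hepatic_group` (`"healthy"`, `"mild"` or `"moderate"`) and `bmi`
#'   (kg/m^2). Extra columns are carried through.
#' @param theta A [theta_table()]; defaults to [theta_reference()].
#' @return A tibble: the input covariates plus columns `cl`, `vc`, `q`,
#'   `vp`, `ra`, `gam1`, `kamax`, `f1`.
#' @examples
#' typical_params(data.frame(hepatic_group = "healthy", bmi = 27))
#' @export
typical_params <- function(covariates, theta = theta_reference()) {
  stopifnot(inherits(theta, "theta_table"))
  if (!is.data.frame(covariates)) {
    stop("`covariates` must be a data frame with columns hepatic_group and bmi",
         call. = FALSE)
  }
  if (!all(c("hepatic_group", "bmi") %in% names(covariates))) {
    stop("`covariates` needs columns `hepatic_group` and `bmi`", call. = FALSE)
  }
  grp <- as.character(covariates$hepatic_group)
  ok <- grp %in% c("healthy", "mild", "moderate")
  if (any(!ok)) {
    stop("unknown hepatic_group: ", paste(unique(grp[!ok]), collapse = ", "),
         call. = FALSE)
  }
  bmi <- as.numeric(covariates$bmi)
  if (any(!is.finite(bmi)) || any(bmi <= 10) || any(bmi >= 60)) {
    stop("`bmi` must lie in (10, 60) kg/m^2", call. = FALSE)
  }
  vp <- theta$vp * (1 + theta$bmi_vp * (bmi - theta$bmi_ref))
  if (any(vp <= 0)) {
    stop("invalid covariate: BMI adjustment drives peripheral volume <= 0",
         call. = FALSE)
  }
  tibble::as_tibble(covariates) |>
    dplyr::mutate(
      cl = unname(theta$cl[grp]),
      vc = theta$vc,
      q = unname(theta$q[grp]),
      vp = vp,
      ra = theta$ra, gam1 = theta$gam1, kamax = theta$kamax, f1 = theta$f1
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
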