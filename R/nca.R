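#' Terminal slope (lambda_z) by best adjusted-R-squared regression
#'
#' Log-linear regression of concentration on time over the terminal points.
#' Candidate windows are the last k = 3..8 positive post-peak
#' concentrations (the peak itself is excluded); the window maximizing the
#' adjusted R-squared is kept, standard pharmacokinetic practice when no
#' selection rule is reported.
#'
#' @param profile A data frame with columns `time` (h) and `conc` (ng/ml).
#' @return A one-row tibble: `lambda_z` (1/h), `n_points_used`,
#'   `adjusted_r2`, `intercept` (log ng/ml at t = 0).
#' @examples
#' prof <- data.frame(time = c(24, 48, 96, 192, 384),
#'                    conc = 1000 * exp(-0.01 * c(24, 48, 96, 192, 384)))
#' fit_lambda_z(prof)
#' @export
fit_lambda_z <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("time", "conc") %in% names(profile)))
  d <- profile[order(profile$time), ]
  ipk <- which.max(d$conc)
  d <- d[-seq_len(ipk), , drop = FALSE]   # strictly post-peak
  d <- d[d$conc > 0, , drop = FALSE]
  if (nrow(d) < 3) {
    stop("lambda_z failure: need >= 3 positive post-peak concentrations",
         call. = FALSE)
  }
  if (stats::sd(log(d$conc)) == 0) {
    stop("lambda_z failure: terminal concentrations show no decline",
         call. = FALSE)
  }
  best <- NULL
  for (k in 3:min(8, nrow(d))) {
    dd <- utils::tail(d, k)
    fit <- stats::lm(log(conc) ~ time, data = dd)
    slope <- stats::coef(fit)[["time"]]
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.finite(ar2) && slope < 0 &&
        (is.null(best) || ar2 > best$adjusted_r2)) {
      best <- tibble::tibble(lambda_z = -slope, n_points_used = k,
                             adjusted_r2 = ar2,
                             intercept = stats::coef(fit)[["(Intercept)"]])
    }
  }
  if (is.null(best)) {
    stop("lambda_z failure: no terminal window with a negative slope",
         call. = FALSE)
  }
  best
}

#' AUC to the last sample by trapezoidal integration
#'
#' Linear-up/log-down trapezoids by default (logarithmic interpolation on
#' declining segments with both endpoints positive, linear otherwise);
#' `method = "linear"` forces plain trapezoids.
#'
#' @inheritParams fit_lambda_z
#' @param method `"lin_up_log_down"` or `"linear"`.
#' @return AUC from the first to the last sample, h*ng/ml.
#' @export
auc_last <- function(profile, method = c("lin_up_log_down", "linear")) {
  method <- match.arg(method)
  d <- profile[order(profile$time), ]
  stopifnot(nrow(d) >= 2)
  t <- d$time
  c1 <- d$conc[-nrow(d)]
  c2 <- d$conc[-1]
  dt <- diff(t)
  seg <- (c1 + c2) / 2 * dt
  if (method == "lin_up_log_down") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
  }
  sum(seg)
}

#' Non-compartmental analysis of one concentration profile
#'
#' Terminal slope by [fit_lambda_z()], AUC to the last positive sample by
#' [auc_last()], extrapolation `AUC_inf = AUC_last + C_last/lambda_z` and
#' `AUC_%ext = 100 * (1 - AUC_last/AUC_inf)`. AUCs are reported in
#' h*mg/liter (1 h*mg/liter = 1000 h*ng/ml).
#'
#' @inheritParams auc_last
#' @return A one-row tibble: `lambda_z` (1/h), `n_points_used`,
#'   `adjusted_r2`, `auc_last`, `auc_inf` (h*mg/liter), `auc_pct_ext` (%),
#'   `c_last` (ng/ml), `t_last` (h).
#' @examples
#' p <- typical_params(data.frame(hepatic_group = "moderate", bmi = 27))
#' times <- c(0.5, 1, 2, 3, 4, 6, 8, 10, 24, 48, 72, 96, 120, 144, 168,
#'            216, 288, 360, 432, 480)
#' prof <- data.frame(time = times,
#'                    conc = conc_iv_infusion(p, 100, 2, times))
#' nca(prof)
#' @export
nca <- function(profile, method = c("lin_up_log_down", "linear")) {
  method <- match.arg(method)
  d <- profile[order(profile$time), ]
  d <- d[d$conc > 0 | d$time < d$time[which.max(d$conc)], , drop = FALSE]
  lz <- fit_lambda_z(d)
  auc <- auc_last(d, method)
  c_last <- d$conc[nrow(d)]
  t_last <- d$time[nrow(d)]
  auc_inf <- auc + c_last / lz$lambda_z
  pct_ext <- 100 * (1 - auc / auc_inf)
  tibble::tibble(
    lambda_z = lz$lambda_z,
    n_points_used = lz$n_points_used,
    adjusted_r2 = lz$adjusted_r2,
    auc_last = auc / 1000,
    auc_inf = auc_inf / 1000,
    auc_pct_ext = pct_ext,
    c_last = c_last,
    t_last = t_last
  )
}

#' Non-compartmental analysis of a study dataset
#'
#' Runs [nca()] on the observed (EVID 0, MDV 0) concentration records of
#' each subject in a NONMEM-style dataset (see
#' [generate_study_dataset()]).
#'
#' @param dataset A study dataset tibble.
#' @param ... Passed to [nca()].
#' @return A tibble with one NCA row per subject plus `ID`, `HEP`, `ROUTE`.
#' @export
nca_dataset <- function(dataset, ...) {
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0, ]
  obs |>
    dplyr::group_by(.data$ID, .data$HEP, .data$ROUTE) |>
    dplyr::group_modify(function(d, key) {
      nca(data.frame(time = d$TIME, conc = d$DV), ...)
    }) |>
    dplyr::ungroup()
}
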