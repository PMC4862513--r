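#' Fit one subject by least squares on log concentrations
#'
#' Minimizes the sum of squared log residuals
#' `sum((log(obs) - log(pred))^2)` over log-transformed structural
#' parameters (so the search is unconstrained and positivity is automatic).
#' Subjects dosed intravenously carry no information on the absorption
#' parameters, so `ra`, `gam1` and `kamax` are held at their initial values
#' and flagged as not estimated. At least three starts are attempted (the
#' supplied initial values plus log-normally perturbed copies) and the best
#' objective is kept.
#'
#' @param events A dose-event data frame: columns `time` (h), `amount`
#'   (mg), `route`, `duration` (h, `NA` for oral).
#' @param obs Observations: data frame with `time` (h) and `conc` (ng/ml),
#'   positive concentrations only.
#' @param init Initial [structural_params()] (or coercible).
#' @param n_starts Number of optimizer starts (>= 1; the published-style
#'   default perturbs two extra starts).
#' @param seed Integer seed for the start perturbations.
#' @param rtol Integration tolerance used for oral predictions during
#'   fitting.
#' @return A list of class `individual_fit`: `params`
#'   ([structural_params()]), `objective`, `convergence` (TRUE if the best
#'   start converged), `n_obs`, `absorption_estimated`.
#' @export
fit_individual <- function(events, obs, init, n_starts = 3, seed = 1,
                           rtol = 1e-8) {
  init <- as_structural_params(init)
  obs <- obs[obs$conc > 0, , drop = FALSE]
  if (nrow(obs) < 8) {
    stop("need >= 8 positive observations to fit a subject", call. = FALSE)
  }
  has_oral <- any(events$route == "oral" & events$amount > 0)
  free <- if (has_oral) c("cl", "vc", "q", "vp", "ra", "gam1", "kamax")
          else c("cl", "vc", "q", "vp")
  logy <- log(obs$conc)
  t_obs <- obs$time

  make_params <- function(logp) {
    p <- as.list(exp(logp))
    names(p) <- free
    out <- unclass(init)
    out[free] <- p
    out
  }
  objective <- function(logp) {
    p <- make_params(logp)
    pred <- tryCatch(predict_conc_events(p, events, t_obs, rtol = rtol),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
    sum((logy - log(pred))^2)
  }

  withr::local_seed(seed)
  start0 <- log(unlist(unclass(init)[free]))
  # generous box (factor ~150 each way) keeps the search out of regions
  # where the absorption ODE becomes needlessly stiff
  lower <- start0 - 5
  upper <- start0 + 5
  starts <- list(start0)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- clip(start0 + stats::rnorm(length(start0), 0, 0.3),
                              lower, upper)
    }
  }
  best <- NULL
  any_ok <- FALSE
  for (st in starts) {
    res <- tryCatch(
      stats::nlminb(st, objective, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000,
                                   rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    any_ok <- TRUE
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (!any_ok) {
    stop("individual fit failed: no optimizer start succeeded", call. = FALSE)
  }
  p <- make_params(best$par)
  structure(list(
    params = structural_params(cl = p$cl, vc = p$vc, q = p$q, vp = p$vp,
                               ra = p$ra, gam1 = p$gam1, kamax = p$kamax,
                               f1 = p$f1),
    objective = best$objective,
    convergence = best$convergence == 0,
    n_obs = nrow(obs),
    absorption_estimated = has_oral
  ), class = "individual_fit")
}

# single-subject prediction over an event table (internal; superpose() is
# the user-facing tibble wrapper without the rtol knob)
predict_conc_events <- function(p, events, times, rtol = 1e-9) {
  conc <- numeric(length(times))
  for (i in seq_len(nrow(events))) {
    amt <- events$amount[i]
    if (amt <= 0) next
    off <- times - events$time[i]
    active <- off > 0
    if (!any(active)) next
    ci <- if (events$route[i] == "iv_infusion") {
      conc_iv_infusion(p, amt, events$duration[i], off[active])
    } else {
      conc_oral_weibull(p, amt, off[active], rtol = rtol)
    }
    conc[active] <- conc[active] + ci
  }
  conc
}

# split a NONMEM-style dataset into per-subject events + observations
dataset_subjects <- function(dataset) {
  ids <- unique(dataset$ID)
  lapply(ids, function(i) {
    d <- dataset[dataset$ID == i, ]
    doses <- d[d$EVID == 1, ]
    route <- names(route_code)[match(d$ROUTE[1], route_code)]
    events <- tibble::tibble(
      time = doses$TIME, amount = doses$AMT, route = route,
      duration = ifelse(doses$RATE > 0, doses$AMT / doses$RATE, NA_real_)
    )
    obs <- d[d$EVID == 0 & d$MDV == 0 & d$DV > 0, ]
    list(
      id = i,
      hepatic_group = names(hep_code)[match(d$HEP[1], hep_code)],
      route = route,
      covariates = tibble::tibble(
        bmi = d$BMI[1], age = d$AGE[1],
        sex = ifelse(d$SEX[1] == 1, "M", "F"), weight = d$WT[1],
        height = d$HT[1], smoker = d$SMOK[1]
      ),
      events = events,
      obs = tibble::tibble(time = obs$TIME, conc = obs$DV)
    )
  })
}

#' Fit every subject of a study dataset
#'
#' Runs [fit_individual()] on each subject of a NONMEM-style dataset.
#' Initial clearance comes from each subject's non-compartmental
#' `dose/AUC_inf` where the terminal fit succeeds (with complete oral
#' bioavailability this is valid for both routes); remaining initial values
#' are round-number disposition constants and the reference absorption
#' constants.
#'
#' @param dataset A study dataset (see [generate_study_dataset()]).
#' @param init Optional [structural_params()] overriding the default
#'   initial values.
#' @param n_starts,seed,rtol Passed to [fit_individual()].
#' @return A tibble with one row per subject: identifiers and covariates,
#'   the estimated parameters `cl` ... `kamax`, `objective`, `convergence`,
#'   `n_obs`, `absorption_estimated`.
#' @export
fit_dataset <- function(dataset, init = NULL, n_starts = 3, seed = 1,
                        rtol = 1e-8) {
  subs <- dataset_subjects(dataset)
  purrr::map_dfr(seq_along(subs), function(k) {
    s <- subs[[k]]
    this_init <- if (!is.null(init)) as_structural_params(init) else {
      cl0 <- tryCatch({
        res <- nca(as.data.frame(s$obs))
        sum(s$events$amount) / res$auc_inf * 1000  # mg / (h*mg/L) -> L/h -> ml/h
      }, error = function(e) 2000)
      if (!is.finite(cl0) || cl0 <= 0) cl0 <- 2000
      structural_params(cl = cl0, vc = 50000, q = 40000, vp = 400000,
                        ra = 0.653, gam1 = 4.57, kamax = 0.86)
    }
    fit <- fit_individual(s$events, s$obs, this_init, n_starts = n_starts,
                          seed = seed + k, rtol = rtol)
    dplyr::bind_cols(
      tibble::tibble(id = s$id, hepatic_group = s$hepatic_group,
                     route = s$route),
      s$covariates,
      tibble::as_tibble(unclass(fit$params)[c("cl", "vc", "q", "vp", "ra",
                                              "gam1", "kamax")]),
      tibble::tibble(objective = fit$objective,
                     convergence = fit$convergence,
                     n_obs = fit$n_obs,
                     absorption_estimated = fit$absorption_estimated)
    )
  })
}

#' Two-stage population estimates from individual fits
#'
#' Pools per-subject estimates into population quantities: typical
#' clearance and intercompartmental clearance are geometric means per
#' hepatic group; central and peripheral volumes are pooled geometric
#' means; absorption parameters are pooled over the subjects for which
#' they were estimable (oral arm). Between-subject variability `omega` is
#' the SD of the log individual estimates (group-centred for `cl` and
#' `q`), and the residual SD is pooled from the individual objectives.
#'
#' A pure two-stage estimator has `SD(eta_hat)/omega_hat = 1` by
#' construction, so eta-shrinkage is only meaningful against an external
#' reference: when `omega_ref` is supplied (e.g. from [theta_reference()]),
#' shrinkage is reported as `100 * (1 - SD(eta_hat)/omega_ref)`, otherwise
#' it is `NA`.
#'
#' @param fits A tibble from [fit_dataset()] (needs >= 5 subjects per
#'   group for the group-specific parameters).
#' @param omega_ref Optional named numeric vector of reference log-scale
#'   SDs (names among `cl, vc, q, vp, ra, gam1, kamax`).
#' @return An object of class `two_stage_fit` with elements `typical`
#'   (tibble: parameter, group, estimate), `omega` (tibble: parameter,
#'   omega, shrinkage), `sigma`, `individual`, `n_subjects`.
#' @export
two_stage_population <- function(fits, omega_ref = NULL) {
  counts <- table(fits$hepatic_group)
  if (any(counts < 5)) {
    stop("need >= 5 subjects per hepatic group for group-specific estimates",
         call. = FALSE)
  }
  gmean <- function(x) exp(mean(log(x)))
  grouped <- purrr::map_dfr(c("cl", "q"), function(par) {
    fits |>
      dplyr::group_by(group = .data$hepatic_group) |>
      dplyr::summarise(estimate = gmean(.data[[par]]), .groups = "drop") |>
      dplyr::mutate(parameter = par, .before = 1)
  })
  abs_fits <- fits[fits$absorption_estimated, ]
  pooled <- tibble::tibble(
    parameter = c("vc", "vp", "ra", "gam1", "kamax"),
    group = NA_character_,
    estimate = c(gmean(fits$vc), gmean(fits$vp),
                 if (nrow(abs_fits) > 0) c(gmean(abs_fits$ra),
                                           gmean(abs_fits$gam1),
                                           gmean(abs_fits$kamax))
                 else rep(NA_real_, 3))
  )
  typical <- dplyr::bind_rows(grouped, pooled)

  eta_of <- function(par) {
    src <- if (par %in% c("ra", "gam1", "kamax")) abs_fits else fits
    if (nrow(src) < 2) return(numeric(0))
    x <- log(src[[par]])
    if (par %in% c("cl", "q")) {
      stats::ave(x, src$hepatic_group, FUN = function(v) v - mean(v))
    } else {
      x - mean(x)
    }
  }
  omega <- purrr::map_dfr(c("cl", "vc", "q", "vp", "ra", "gam1", "kamax"),
    function(par) {
      eta <- eta_of(par)
      om <- if (length(eta) >= 2) stats::sd(eta) else NA_real_
      shr <- if (!is.null(omega_ref) && par %in% names(omega_ref) &&
                 is.finite(om)) {
        clip(100 * (1 - om / omega_ref[[par]]), 0, 100)
      } else NA_real_
      tibble::tibble(parameter = par, omega = om, shrinkage = shr)
    })

  sigma <- sqrt(sum(fits$objective) / sum(fits$n_obs))
  structure(list(typical = typical, omega = omega, sigma = sigma,
                 individual = fits, n_subjects = nrow(fits)),
            class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("<two_stage_fit> ", x$n_subjects, " subjects\n", sep = "")
  print(x$typical, n = Inf)
  cat(sprintf("sigma (log-SD): %.4f\n", x$sigma))
  invisible(x)
}

#' @rdname two_stage_population
#' @param x A `two_stage_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.two_stage_fit <- function(x, ...) {
  dplyr::left_join(x$typical, x$omega, by = "parameter")
}

#' @rdname two_stage_population
#' @exportS3Method generics::glance
glance.two_stage_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_obs = sum(x$individual$n_obs),
    objective = sum(x$individual$objective),
    sigma = x$sigma,
    converged = mean(x$individual$convergence)
  )
}

default_scm_candidates <- function() {
  tibble::tibble(
    parameter = c("cl", "q", "vp",
                  rep("cl", 5), rep("vp", 5)),
    covariate = c("hepatic_group", "hepatic_group", "bmi",
                  rep(c("age", "sex", "weight", "height", "smoker"), 2))
  )
}

#' Stepwise covariate selection on individual estimates
#'
#' Forward-inclusion / backward-elimination search over
#' covariate-parameter relations. Each relation is tested by a
#' likelihood-ratio test (`n * log(RSS0/RSS1)` compared to a chi-squared
#' with as many degrees of freedom as added coefficients; a three-level
#' hepatic group adds 2, continuous or binary covariates add 1) on
#' regressions of the log individual parameter estimates from the first
#' stage -- one independent datum per subject, which keeps the test
#' calibrated in the presence of between-subject variability. Forward
#' steps add the smallest-p candidate with `p < p_in` until none
#' qualifies; backward steps then remove relations with `p > p_out` one at
#' a time, worst first.
#'
#' @param fits A tibble from [fit_dataset()] including covariate columns.
#' @param candidates A data frame with columns `parameter` and
#'   `covariate`; defaults to hepatic group on `cl` and `q`, BMI on `vp`,
#'   and the inert demographics on `cl` and `vp`.
#' @param p_in Forward-inclusion threshold (default 0.01).
#' @param p_out Backward-retention threshold (default 0.001).
#' @return An object of class `scm_result`: `steps` (tibble: phase,
#'   parameter, covariate, delta_ofv, df, p_value, action), `included`
#'   (tibble of retained relations), `ofv` (final total objective).
#' @export
stepwise_covariate_selection <- function(fits,
                                         candidates = default_scm_candidates(),
                                         p_in = 0.01, p_out = 0.001) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) > 0 &&
      !all(c("parameter", "covariate") %in% names(candidates))) {
    stop("`candidates` needs columns `parameter` and `covariate`",
         call. = FALSE)
  }
  n <- nrow(fits)
  fit_lm <- function(parameter, covs) {
    rhs <- if (length(covs) == 0) "1" else paste(covs, collapse = " + ")
    stats::lm(stats::as.formula(paste0("log(", parameter, ") ~ ", rhs)),
              data = fits)
  }
  rss <- function(m) sum(stats::resid(m)^2)
  ofv_of <- function(m) n * log(rss(m) / n)
  lrt <- function(m_small, m_big) {
    df <- length(stats::coef(m_big)) - length(stats::coef(m_small))
    if (df <= 0) stop("non-nested comparison in covariate search", call. = FALSE)
    d_ofv <- n * log(rss(m_small) / rss(m_big))
    list(delta_ofv = d_ofv, df = df,
         p = stats::pchisq(d_ofv, df, lower.tail = FALSE))
  }

  included <- candidates[0, , drop = FALSE]
  pool <- candidates
  if (nrow(pool) > 0) {
    missing_cov <- setdiff(unique(pool$covariate), names(fits))
    if (length(missing_cov) > 0) {
      stop("covariate column(s) not in `fits`: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    # a covariate constant across subjects carries no information and
    # would break the design matrix; drop it from the search
    constant <- vapply(pool$covariate,
                       function(cv) length(unique(fits[[cv]])) < 2,
                       logical(1))
    pool <- pool[!constant, , drop = FALSE]
  }
  steps <- list()
  # forward inclusion
  repeat {
    if (nrow(pool) == 0) break
    trials <- purrr::map_dfr(seq_len(nrow(pool)), function(i) {
      par <- pool$parameter[i]
      covs0 <- included$covariate[included$parameter == par]
      t <- lrt(fit_lm(par, covs0), fit_lm(par, c(covs0, pool$covariate[i])))
      tibble::tibble(parameter = par, covariate = pool$covariate[i],
                     delta_ofv = t$delta_ofv, df = t$df, p_value = t$p)
    })
    best <- trials[which.min(trials$p_value), ]
    if (best$p_value >= p_in) {
      steps[[length(steps) + 1]] <- dplyr::mutate(
        trials, phase = "forward", action = "rejected")
      break
    }
    steps[[length(steps) + 1]] <- dplyr::mutate(
      best, phase = "forward", action = "included")
    included <- dplyr::bind_rows(included, best[, c("parameter", "covariate")])
    pool <- dplyr::anti_join(pool, best[, c("parameter", "covariate")],
                             by = c("parameter", "covariate"))
  }
  # backward elimination
  repeat {
    if (nrow(included) == 0) break
    trials <- purrr::map_dfr(seq_len(nrow(included)), function(i) {
      par <- included$parameter[i]
      covs_full <- included$covariate[included$parameter == par]
      covs_red <- setdiff(covs_full, included$covariate[i])
      t <- lrt(fit_lm(par, covs_red), fit_lm(par, covs_full))
      tibble::tibble(parameter = par, covariate = included$covariate[i],
                     delta_ofv = t$delta_ofv, df = t$df, p_value = t$p)
    })
    worst <- trials[which.max(trials$p_value), ]
    if (worst$p_value <= p_out) break
    steps[[length(steps) + 1]] <- dplyr::mutate(
      worst, phase = "backward", action = "removed")
    included <- dplyr::anti_join(included,
                                 worst[, c("parameter", "covariate")],
                                 by = c("parameter", "covariate"))
  }

  params <- unique(c(candidates$parameter, "cl", "q", "vp"))
  total_ofv <- sum(vapply(params, function(par) {
    ofv_of(fit_lm(par, included$covariate[included$parameter == par]))
  }, numeric(1)))
  steps <- if (length(steps) > 0) dplyr::bind_rows(steps) else
    tibble::tibble(parameter = character(), covariate = character(),
                   delta_ofv = numeric(), df = numeric(),
                   p_value = numeric(), phase = character(),
                   action = character())
  structure(list(steps = steps, included = included, ofv = total_ofv),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("<scm_result>\n")
  if (nrow(x$included) == 0) {
    cat("  no covariates retained (base model)\n")
  } else {
    for (i in seq_len(nrow(x$included))) {
      cat(sprintf("  %s ~ %s\n", x$included$parameter[i],
                  x$included$covariate[i]))
    }
  }
  invisible(x)
}

#' @rdname stepwise_covariate_selection
#' @param x An `scm_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.scm_result <- function(x, ...) x$steps

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples subjects with replacement, stratified by hepatic group,
#' re-pools the two-stage population estimates on each replicate, and
#' reports percentile intervals and bootstrap means. In the two-stage
#' estimator the individual fits do not change under subject resampling,
#' so replicate refits reduce to re-pooling the resampled individual
#' estimates, which makes the published 500 replications cheap.
#'
#' @param fits A tibble from [fit_dataset()].
#' @param n_rep Number of bootstrap replicates (>= 2; 500 in the published
#'   validation).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param omega_ref Passed to [two_stage_population()].
#' @return A tibble: `parameter`, `group`, `estimate` (original),
#'   `boot_mean`, `lower`, `upper`, `n_rep`. Attribute `"n_failed"` counts
#'   replicates whose pooling failed; a warning is attached when more than
#'   20% fail.
#' @export
bootstrap_ci <- function(fits, n_rep = 500, seed = 1, level = 0.95,
                         omega_ref = NULL) {
  stopifnot(n_rep >= 2, level > 0, level < 1)
  full <- two_stage_population(fits, omega_ref = omega_ref)
  withr::local_seed(seed)
  groups <- split(seq_len(nrow(fits)), fits$hepatic_group)
  reps <- vector("list", n_rep)
  n_failed <- 0
  for (r in seq_len(n_rep)) {
    idx <- unlist(lapply(groups, function(g) sample(g, length(g),
                                                    replace = TRUE)))
    rep_est <- tryCatch(
      two_stage_population(fits[idx, ], omega_ref = omega_ref)$typical,
      error = function(e) NULL)
    if (is.null(rep_est)) { n_failed <- n_failed + 1; next }
    reps[[r]] <- dplyr::mutate(rep_est, rep = r)
  }
  if (n_failed > 0.2 * n_rep) {
    warning("bootstrap quality: ", n_failed, " of ", n_rep,
            " replicates failed to converge")
  }
  boot <- dplyr::bind_rows(reps)
  a <- (1 - level) / 2
  out <- boot |>
    dplyr::group_by(.data$parameter, .data$group) |>
    dplyr::summarise(
      boot_mean = mean(.data$estimate),
      lower = stats::quantile(.data$estimate, a, names = FALSE,
                              na.rm = TRUE),
      upper = stats::quantile(.data$estimate, 1 - a, names = FALSE,
                              na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::left_join(x = full$typical, y = _, by = c("parameter", "group")) |>
    dplyr::mutate(n_rep = n_rep)
  attr(out, "n_failed") <- n_failed
  out
}

#' Normalized prediction distribution errors
#'
#' Simulation-based residual diagnostics: the model (a parameter table plus
#' the study design embedded in the dataset) is used to simulate `n_sim`
#' replicate datasets; each observation's prediction discrepancy is
#' decorrelated within subject using the simulation-estimated mean and
#' covariance (Cholesky factor) of the log concentrations, and its
#' mid-rank percentile among the decorrelated simulations is mapped
#' through the standard-normal quantile function. Under the true model the
#' scores are standard normal. Ties are broken by a small seeded jitter;
#' boundary ranks map to `1/(2*n_sim)` and `1 - 1/(2*n_sim)`.
#'
#' @param dataset An observed study dataset (see
#'   [generate_study_dataset()]).
#' @param theta The evaluation model, a [theta_table()].
#' @param n_sim Number of simulation replicates (>= 50; 1,000 is the
#'   published choice).
#' @param seed Integer seed.
#' @return An object of class `npde_result`: `scores` (tibble: id, time,
#'   npde), `mean`, `variance`, `shapiro_p`, `t_p` (mean-zero t-test),
#'   `var_p` (variance-one chi-squared test), `p_global` (Bonferroni of
#'   the three), `n_sim`.
#' @export
npde <- function(dataset, theta = theta_reference(), n_sim = 1000, seed = 1) {
  if (n_sim < 50) {
    stop("`n_sim` must be >= 50 (rank resolution too coarse below that)",
         call. = FALSE)
  }
  stopifnot(inherits(theta, "theta_table"))
  subs <- dataset_subjects(dataset)
  withr::local_seed(seed)
  om <- theta$omega
  scores <- purrr::map_dfr(subs, function(s) {
    m <- nrow(s$obs)
    if (m == 0) return(NULL)
    typ <- typical_params(
      tibble::tibble(hepatic_group = s$hepatic_group, bmi = s$covariates$bmi),
      theta)
    eta <- matrix(stats::rnorm(n_sim * length(om), 0, rep(om, each = n_sim)),
                  nrow = n_sim, dimnames = list(NULL, names(om)))
    logsim <- matrix(NA_real_, n_sim, m)
    iv <- s$route == "iv_infusion"
    dose <- sum(s$events$amount)
    dur <- s$events$duration[1]
    if (iv) {
      logsim <- log(sim_iv_matrix(
        cl = typ$cl * exp(eta[, "cl"]), vc = typ$vc * exp(eta[, "vc"]),
        q = typ$q * exp(eta[, "q"]), vp = typ$vp * exp(eta[, "vp"]),
        dose = dose, duration = dur, times = s$obs$time))
    } else {
      for (k in seq_len(n_sim)) {
        p <- list(cl = typ$cl * exp(eta[k, "cl"]),
                  vc = typ$vc * exp(eta[k, "vc"]),
                  q = typ$q * exp(eta[k, "q"]),
                  vp = typ$vp * exp(eta[k, "vp"]),
                  ra = typ$ra * exp(eta[k, "ra"]),
                  gam1 = typ$gam1 * exp(eta[k, "gam1"]),
                  kamax = typ$kamax * exp(eta[k, "kamax"]), f1 = typ$f1)
        logsim[k, ] <- log(conc_oral_weibull(p, dose, s$obs$time,
                                             rtol = 1e-8))
      }
    }
    logsim <- logsim + matrix(stats::rnorm(n_sim * m, 0, theta$sigma),
                              n_sim, m)
    mu <- colMeans(logsim)
    V <- stats::cov(logsim)
    L <- t(chol(V + diag(1e-10 * mean(diag(V)), m)))
    centered <- t(logsim) - mu                  # m x n_sim
    dsim <- forwardsolve(L, centered)           # m x n_sim
    dobs <- forwardsolve(L, log(s$obs$conc) - mu)
    jit <- 1e-9 * stats::sd(dsim)
    dsim <- dsim + stats::runif(length(dsim), -jit, jit)
    dobs <- dobs + stats::runif(length(dobs), -jit, jit)
    r <- rowSums(dsim < dobs)                   # per-observation rank
    p <- clip((r + 0.5) / n_sim, 0.5 / n_sim, 1 - 0.5 / n_sim)
    tibble::tibble(id = s$id, time = s$obs$time, npde = stats::qnorm(p))
  })
  x <- scores$npde
  n <- length(x)
  if (n >= 3) {
    t_p <- stats::t.test(x)$p.value
    var_stat <- (n - 1) * stats::var(x)
    var_p <- 2 * min(stats::pchisq(var_stat, n - 1),
                     stats::pchisq(var_stat, n - 1, lower.tail = FALSE))
    shapiro_p <- stats::shapiro.test(if (n > 5000) sample(x, 5000) else
                                       x)$p.value
    p_global <- min(1, 3 * min(t_p, var_p, shapiro_p))
  } else {
    t_p <- var_p <- shapiro_p <- p_global <- NA_real_
  }
  structure(list(
    scores = scores, mean = mean(x),
    variance = if (n >= 2) stats::var(x) else NA_real_,
    shapiro_p = shapiro_p, t_p = t_p, var_p = var_p,
    p_global = p_global, n_sim = n_sim
  ), class = "npde_result")
}

# closed-form iv infusion concentrations for vectors of subjects
# (rows = parameter draws, cols = times)
sim_iv_matrix <- function(cl, vc, q, vp, dose, duration, times) {
  d <- disp_vec(cl, vc, q, vp)
  r0 <- dose * 1e6 / duration
  term <- function(lam, coef) {
    during <- (1 - exp(-outer(lam, pmin(times, duration)))) / lam
    decay <- exp(-outer(lam, pmax(times - duration, 0)))
    coef * during * decay
  }
  (r0 / vc) * (term(d$alpha, d$ca) + term(d$beta, d$cb))
}

#' @export
print.npde_result <- function(x, ...) {
  cat("<npde_result>\n")
  cat(sprintf("  %d scores, %d simulation replicates\n",
              nrow(x$scores), x$n_sim))
  cat(sprintf("  mean %.3f, variance %.3f, global p %.3g\n",
              x$mean, x$variance, x$p_global))
  invisible(x)
}

#' @rdname npde
#' @param x An `npde_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.npde_result <- function(x, ...) x$scores

#' @rdname npde
#' @exportS3Method generics::glance
glance.npde_result <- function(x, ...) {
  tibble::tibble(mean = x$mean, variance = x$variance,
                 shapiro_p = x$shapiro_p, t_p = x$t_p, var_p = x$var_p,
                 p_global = x$p_global, n = nrow(x$scores),
                 n_sim = x$n_sim)
}
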