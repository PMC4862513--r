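#' Specification of the two phase-1 hepatic-impairment studies
#'
#' Captures the study design used for cohort and dataset generation: three
#' hepatic-function groups (healthy, mild, moderate Child-Pugh impairment),
#' two parallel studies (alcoholic-cirrhosis and hepatitis-B/C etiology)
#' contributing half of each group, a 50/50 split between oral dosing and
#' 2-h intravenous infusion, a single 100-mg dose, and 21 scheduled
#' sampling times from predose to 480 h.
#'
#' Demographic envelopes follow the published baseline tables: age 37-64 y,
#' BMI 21-34 kg/m^2, weight 53-107 kg, 21 male / 11 female per group of 32,
#' with healthy controls matched to impaired subjects within +/-7 years,
#' +/-8 kg and +/-4 kg/m^2 and of the same sex. Child-Pugh laboratory
#' values (bilirubin, albumin, prothrombin, score) are drawn per
#' etiology/severity from the published means and SDs and carried as inert
#' covariates.
#'
#' @param n_per_group Subjects per hepatic group (split evenly across the
#'   two studies); the published studies used 32.
#' @param dose Dose, mg (isavuconazole equivalents).
#' @param infusion_duration Infusion duration, h.
#' @param times Scheduled sampling times, h, including the predose sample
#'   at 0.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(n_per_group = 32, dose = 100, infusion_duration = 2,
                       times = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 24, 48, 72,
                                 96, 120, 144, 168, 216, 288, 360, 432, 480)) {
  stopifnot(n_per_group >= 2, n_per_group %% 2 == 0, dose > 0,
            infusion_duration > 0, !is.unsorted(times, strictly = TRUE))
  structure(list(
    n_per_group = n_per_group,
    dose = dose,
    infusion_duration = infusion_duration,
    times = times,
    groups = c("healthy", "mild", "moderate"),
    male_per_group = round(21 / 32 * n_per_group),
    smokers_per_group = round(c(healthy = 19, mild = 24, moderate = 24) / 32 *
                                n_per_group),
    age_range = c(37, 64), age_range_healthy = c(40, 64),
    height_range = c(159, 177),
    bmi_range = c(21, 34), bmi_range_healthy = c(22, 33),
    weight_range = c(53, 107),
    match_tol = c(age = 7, weight = 8, bmi = 4),
    # Child-Pugh labs: mean/SD by etiology x severity
    cp_labs = list(
      alcoholic = list(
        mild = c(bili = 21.03, bili_sd = 10.12, alb = 4.46, alb_sd = 0.41,
                 pt = 1.11, pt_sd = 0.16, cp = 5.18, cp_sd = 0.43),
        moderate = c(bili = 49.47, bili_sd = 29.02, alb = 3.76, alb_sd = 0.52,
                     pt = 1.28, pt_sd = 0.27, cp = 7.43, cp_sd = 0.72)
      ),
      hepatitis = list(
        mild = c(bili = 82.30, bili_sd = 38.43, alb = 4.07, alb_sd = 0.44,
                 pt = 1.56, pt_sd = 0.97, cp = 5.75, cp_sd = 0.44),
        moderate = c(bili = 128.18, bili_sd = 39.10, alb = 3.13, alb_sd = 0.37,
                     pt = 3.20, pt_sd = 1.25, cp = 8.31, cp_sd = 0.70)
      )
    )
  ), class = "study_spec")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a matched study cohort
#'
#' Draws demographics for `n_per_group` subjects per hepatic group,
#' organized as matched triplets: a healthy control is drawn first and the
#' mild and moderate subjects of the same triplet share its sex and height
#' and differ by at most the matching tolerances in age, weight and BMI
#' (clipping to the demographic envelopes only moves values towards the
#' control, so the constraints hold by construction). Healthy-subject
#' Child-Pugh laboratory values are synthetic normal-range draws (the
#' published tables cover the impaired groups only); all labs are inert
#' covariates with no PK effect.
#'
#' @param spec A [study_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject: `id`, `study`, `etiology`,
#'   `hepatic_group`, `match_id`, `sex`, `age`, `weight`, `height`, `bmi`,
#'   `smoker`, `bilirubin`, `albumin`, `prothrombin`, `cp_score`, `route`.
#' @export
generate_cohort <- function(spec = study_spec(), seed) {
  withr::local_seed(seed)
  n_trip <- spec$n_per_group / 2          # triplets per study
  m_tot <- spec$male_per_group
  males_study <- c(ceiling(m_tot / 2), floor(m_tot / 2))
  etiologies <- c("alcoholic", "hepatitis")

  rows <- list()
  for (s in 1:2) {
    sexes <- sample(rep(c("M", "F"),
                        c(males_study[s], n_trip - males_study[s])))
    for (i in seq_len(n_trip)) {
      ht <- stats::runif(1, spec$height_range[1], spec$height_range[2])
      h2 <- (ht / 100)^2
      age_h <- stats::runif(1, spec$age_range_healthy[1],
                            spec$age_range_healthy[2])
      bmi_h <- stats::runif(1, spec$bmi_range_healthy[1],
                            spec$bmi_range_healthy[2])
      bmax <- min(spec$match_tol[["bmi"]],
                  (spec$match_tol[["weight"]] - 0.1) / h2)
      impaired <- function(group) {
        age <- clip(age_h + stats::runif(1, -spec$match_tol[["age"]],
                                         spec$match_tol[["age"]]),
                    spec$age_range[1], spec$age_range[2])
        bmi <- clip(bmi_h + stats::runif(1, -bmax, bmax),
                    spec$bmi_range[1], spec$bmi_range[2])
        lab <- spec$cp_labs[[etiologies[s]]][[group]]
        tibble::tibble(
          study = s, etiology = etiologies[s], hepatic_group = group,
          sex = sexes[i], age = age, height = ht, bmi = bmi,
          weight = bmi * h2,
          bilirubin = max(stats::rnorm(1, lab[["bili"]], lab[["bili_sd"]]), 1),
          albumin = max(stats::rnorm(1, lab[["alb"]], lab[["alb_sd"]]), 1),
          prothrombin = max(stats::rnorm(1, lab[["pt"]], lab[["pt_sd"]]), 0.8),
          cp_score = max(stats::rnorm(1, lab[["cp"]], lab[["cp_sd"]]), 5)
        )
      }
      healthy <- tibble::tibble(
        study = s, etiology = etiologies[s], hepatic_group = "healthy",
        sex = sexes[i], age = age_h, height = ht, bmi = bmi_h,
        weight = bmi_h * h2,
        bilirubin = max(stats::rnorm(1, 8, 3), 2),
        albumin = stats::rnorm(1, 4.5, 0.3),
        prothrombin = stats::rnorm(1, 1.0, 0.05),
        cp_score = 5
      )
      trip <- dplyr::bind_rows(healthy, impaired("mild"), impaired("moderate"))
      trip$triplet <- paste(s, i)
      rows[[length(rows) + 1]] <- trip
    }
  }
  cohort <- dplyr::bind_rows(rows)

  # smoking: exact counts per group; route: balanced 50/50 within study x group
  cohort <- cohort |>
    dplyr::group_by(.data$hepatic_group) |>
    dplyr::mutate(smoker = as.integer(sample(rep(
      c(1L, 0L),
      c(spec$smokers_per_group[[unique(.data$hepatic_group)]],
        dplyr::n() - spec$smokers_per_group[[unique(.data$hepatic_group)]])
    )))) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$study, .data$hepatic_group) |>
    dplyr::mutate(route = sample(rep(c("iv_infusion", "oral"),
                                     length.out = dplyr::n()))) |>
    dplyr::ungroup()

  cohort <- cohort |>
    dplyr::arrange(.data$study, .data$triplet, .data$hepatic_group) |>
    dplyr::mutate(id = dplyr::row_number())
  match_ids <- cohort |>
    dplyr::filter(.data$hepatic_group == "healthy") |>
    dplyr::select("triplet", match_id = "id")
  cohort |>
    dplyr::left_join(match_ids, by = "triplet") |>
    dplyr::select("id", "study", "etiology", "hepatic_group", "match_id",
                  "sex", "age", "weight", "height", "bmi", "smoker",
                  "bilirubin", "albumin", "prothrombin", "cp_score", "route")
}

hep_code <- c(healthy = 0L, mild = 1L, moderate = 2L)
route_code <- c(iv_infusion = 1L, oral = 2L)

#' Generate a NONMEM-style longitudinal study dataset
#'
#' For each cohort subject: samples log-scale random effects from the
#' omegas of `theta`, builds individual structural parameters, simulates
#' the single dose by the assigned route at the scheduled sampling times,
#' and applies additive log-scale residual error. The long-format event
#' table has one dose row plus one observation row per scheduled time per
#' subject; the predose sample is emitted as `DV = 0` with `MDV = 1`.
#'
#' Column coding: `EVID` 1 dose / 0 observation; `MDV` 1 missing; `CMT` 1
#' depot / 2 central; `SEX` 1 male / 2 female; `ROUTE` 1 iv infusion / 2
#' oral; `HEP` 0 healthy / 1 mild / 2 moderate; `DV` ng/ml; `AMT` mg;
#' `RATE` mg/h.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param theta A [theta_table()].
#' @param spec The [study_spec()] used for the cohort.
#' @param seed Integer seed.
#' @return A tibble with columns `ID, TIME, AMT, RATE, EVID, MDV, CMT, DV,
#'   HEP, BMI, AGE, SEX, WT, HT, SMOK, BILI, ALB, PT, ROUTE, STUDY`.
#' @examples
#' spec <- study_spec(n_per_group = 4)
#' cohort <- generate_cohort(spec, seed = 1)
#' ds <- generate_study_dataset(cohort, theta_reference(), spec, seed = 2)
#' @export
generate_study_dataset <- function(cohort, theta = theta_reference(),
                                   spec = study_spec(), seed) {
  withr::local_seed(seed)
  n <- nrow(cohort)
  typ <- typical_params(cohort, theta)
  om <- theta$omega
  pnames <- names(om)
  eta <- matrix(stats::rnorm(n * length(om), 0, rep(om, each = n)),
                nrow = n, dimnames = list(NULL, pnames))
  ind <- typ
  for (nm in pnames) ind[[nm]] <- ind[[nm]] * exp(eta[, nm])

  tpost <- spec$times[spec$times > 0]
  purrr::map_dfr(seq_len(n), function(i) {
    sub <- ind[i, ]
    pred <- if (sub$route == "iv_infusion") {
      conc_iv_infusion(sub, spec$dose, spec$infusion_duration, tpost)
    } else {
      conc_oral_weibull(sub, spec$dose, tpost)
    }
    eps <- stats::rnorm(length(tpost), 0, theta$sigma)
    dv <- ifelse(pred > 0, exp(log(pmax(pred, .Machine$double.xmin)) + eps), 0)
    dv_full <- numeric(length(spec$times))
    dv_full[spec$times > 0] <- dv
    base <- tibble::tibble(
      ID = sub$id,
      HEP = hep_code[[sub$hepatic_group]], BMI = sub$bmi, AGE = sub$age,
      SEX = if (sub$sex == "M") 1L else 2L, WT = sub$weight, HT = sub$height,
      SMOK = sub$smoker, BILI = sub$bilirubin, ALB = sub$albumin,
      PT = sub$prothrombin, ROUTE = route_code[[sub$route]], STUDY = sub$study
    )
    iv <- sub$route == "iv_infusion"
    dose_row <- dplyr::mutate(base,
      TIME = 0, AMT = spec$dose,
      RATE = if (iv) spec$dose / spec$infusion_duration else 0,
      EVID = 1L, MDV = 1L, CMT = if (iv) 2L else 1L, DV = 0)
    obs_rows <- dplyr::bind_cols(
      base[rep(1, length(spec$times)), ],
      tibble::tibble(
        TIME = spec$times, AMT = 0, RATE = 0, EVID = 0L,
        MDV = as.integer(spec$times == 0), CMT = 2L,
        DV = dv_full
      )
    )
    dplyr::bind_rows(dose_row, obs_rows) |>
      dplyr::select("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "CMT", "DV",
                    "HEP", "BMI", "AGE", "SEX", "WT", "HT", "SMOK", "BILI",
                    "ALB", "PT", "ROUTE", "STUDY")
  })
}

#' Read or write a study dataset as CSV
#'
#' Plain-CSV round trip for the NONMEM-style event table produced by
#' [generate_study_dataset()].
#'
#' @param dataset A study dataset tibble.
#' @param path File path.
#' @return `read_study_dataset()` returns the dataset tibble;
#'   `write_study_dataset()` returns `path` invisibly.
#' @export
write_study_dataset <- function(dataset, path) {
  readr::write_csv(dataset, path)
  invisible(path)
}

#' @rdname write_study_dataset
#' @export
read_study_dataset <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    ID = "i", EVID = "i", MDV = "i", CMT = "i", SEX = "i",
                    SMOK = "i", ROUTE = "i", STUDY = "i",
                    .default = readr::col_double()
                  ))
}
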