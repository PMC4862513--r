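test_that("noise-free subjects are recovered almost exactly", {
  p_true <- typ_group("mild")
  # iv arm
  s <- sim_iv_subject(p_true, sigma = 0)
  init <- structural_params(cl = 2000, vc = 40000, q = 30000, vp = 3e5)
  fit <- fit_individual(s$events, s$obs, init, n_starts = 2, seed = 1)
  expect_equal(fit$params$cl, p_true$cl, tolerance = 0.01)
  expect_equal(fit$params$vc, p_true$vc, tolerance = 0.02)
  expect_false(fit$absorption_estimated)
  # oral arm (absorption constants free)
  obs_o <- tibble::tibble(time = study_times(),
                          conc = conc_oral_weibull(p_true, 100, study_times()))
  ev_o <- tibble::tibble(time = 0, amount = 100, route = "oral",
                         duration = NA_real_)
  init_o <- structural_params(cl = 2000, vc = 40000, q = 30000, vp = 3e5,
                              ra = 0.6, gam1 = 4, kamax = 1)
  fit_o <- fit_individual(ev_o, obs_o, init_o, n_starts = 2, seed = 2)
  expect_equal(fit_o$params$cl, p_true$cl, tolerance = 0.01)
  expect_true(fit_o$absorption_estimated)
})

test_that("starting at the truth on noise-free data leaves the objective at zero", {
  p_true <- typ_group("healthy")
  s <- sim_iv_subject(p_true, sigma = 0)
  fit <- fit_individual(s$events, s$obs, p_true, n_starts = 1)
  expect_lt(fit$objective, 1e-8)
})

test_that("too few observations raise an error", {
  p <- typ_group("healthy")
  s <- sim_iv_subject(p, times = c(1, 2, 4, 8, 24))
  expect_error(fit_individual(s$events, s$obs, p), ">= 8")
})

test_that("the fitter is calibrated: CL within 15% for nearly all noisy subjects", {
  p_true <- typ_group("healthy")
  init <- structural_params(cl = 2000, vc = 40000, q = 30000, vp = 3e5)
  hits <- vapply(1:100, function(i) {
    s <- sim_iv_subject(p_true, sigma = 0.1788, seed = 1000 + i)
    fit <- fit_individual(s$events, s$obs, init, n_starts = 1)
    abs(fit$params$cl / p_true$cl - 1) < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("two-stage pooling recovers group structure and handles degenerate variability", {
  # a single-group dataset: group-specific and pooled estimates coincide
  ds1 <- make_iv_dataset(cl = rep(2540, 6), group = rep("healthy", 6),
                         sigma = 0.05, seed = 21)
  fits1 <- fit_dataset(ds1, n_starts = 1, seed = 22)
  ts1 <- two_stage_population(fits1, omega_ref = theta_reference()$omega)
  cl_grp <- ts1$typical$estimate[ts1$typical$parameter == "cl"]
  expect_equal(exp(mean(log(fits1$cl))), cl_grp, tolerance = 1e-12)
  # omega = 0 generation: estimated omega near the fitter noise floor,
  # shrinkage against the reference omega is high
  om_cl <- ts1$omega$omega[ts1$omega$parameter == "cl"]
  expect_lt(om_cl, 0.08)
  expect_gt(ts1$omega$shrinkage[ts1$omega$parameter == "cl"], 50)
  expect_error(two_stage_population(fits1[1:4, ]), ">= 5 subjects")
})

test_that("stepwise covariate selection recovers the hepatic effect on clearance", {
  withr::local_seed(31)
  cl_true <- c(healthy = 2540, mild = 1550, moderate = 1326)
  group <- rep(names(cl_true), each = 8)
  cl_i <- cl_true[group] * exp(stats::rnorm(24, 0, 0.4347))
  ds <- make_iv_dataset(cl = cl_i, group = group, sigma = 0.1788, seed = 32)
  fits <- fit_dataset(ds, n_starts = 1, seed = 33)
  fits$bmi <- stats::runif(24, 21, 34)   # inert here
  scm <- stepwise_covariate_selection(fits)
  expect_true(any(scm$included$parameter == "cl" &
                    scm$included$covariate == "hepatic_group"))
  # accepted forward steps strictly reduce the objective
  fwd <- scm$steps[scm$steps$phase == "forward" &
                     scm$steps$action == "included", ]
  expect_true(all(fwd$delta_ofv > 0))
  expect_true(all(fwd$p_value < 0.01))
})

test_that("an empty candidate list returns the base model unchanged", {
  ds <- make_iv_dataset(cl = rep(2000, 6), group = rep("healthy", 6),
                        sigma = 0.1, seed = 41)
  fits <- fit_dataset(ds, n_starts = 1, seed = 42)
  fits$bmi <- 27
  empty <- data.frame(parameter = character(), covariate = character())
  scm <- stepwise_covariate_selection(fits, candidates = empty)
  expect_equal(nrow(scm$included), 0)
  expect_equal(nrow(scm$steps[scm$steps$action == "included", ]), 0)
})

test_that("bootstrap percentile machinery degenerates to zero width on constant input", {
  one <- make_iv_dataset(cl = 2500, group = "healthy", sigma = 0.05, seed = 51)
  fit1 <- fit_dataset(one, n_starts = 1, seed = 52)
  fits <- fit1[rep(1, 6), ]
  fits$id <- 1:6
  bs <- bootstrap_ci(fits, n_rep = 10, seed = 53)
  expect_equal(bs$lower, bs$upper, tolerance = 1e-12)
  expect_equal(bs$boot_mean, bs$estimate, tolerance = 1e-12)
})

test_that("bootstrap intervals cover the generating clearance and widen with fewer subjects", {
  withr::local_seed(61)
  make_fits <- function(n_per_group, seed) {
    group <- rep(c("healthy", "mild", "moderate"), each = n_per_group)
    cl_true <- c(healthy = 2540, mild = 1550, moderate = 1326)
    cl_i <- cl_true[group] * exp(stats::rnorm(length(group), 0, 0.4347))
    ds <- make_iv_dataset(cl = cl_i, group = group, sigma = 0.1788,
                          seed = seed)
    fit_dataset(ds, n_starts = 1, seed = seed + 1)
  }
  fits16 <- make_fits(16, 62)
  # half the subjects per group, keeping every other clearance rank so the
  # subset's spread matches the full sample and only n changes
  fits8 <- dplyr::bind_rows(lapply(split(fits16, fits16$hepatic_group),
                                   function(d) d[order(d$cl)[seq(1, 16, 2)], ]))
  bs16 <- bootstrap_ci(fits16, n_rep = 200, seed = 63)
  bs8 <- bootstrap_ci(fits8, n_rep = 200, seed = 64)
  h16 <- bs16[bs16$parameter == "cl" & bs16$group == "healthy", ]
  h8 <- bs8[bs8$parameter == "cl" & bs8$group == "healthy", ]
  expect_true(h16$lower <= 2540 && 2540 <= h16$upper)
  expect_gt(h8$upper - h8$lower, h16$upper - h16$lower)
})

test_that("bootstrap coverage of the 95% interval is near nominal", {
  cl_true <- c(healthy = 2540, mild = 1550, moderate = 1326)
  covered <- vapply(1:50, function(r) {
    withr::local_seed(700 + r)
    group <- rep(names(cl_true), each = 12)
    cl_i <- cl_true[group] * exp(stats::rnorm(36, 0, 0.4347))
    ds <- make_iv_dataset(cl = cl_i, group = group, sigma = 0.1788,
                          seed = 800 + r)
    fits <- fit_dataset(ds, n_starts = 1, seed = 900 + r)
    bs <- bootstrap_ci(fits, n_rep = 150, seed = 1000 + r)
    h <- bs[bs$parameter == "cl" & bs$group == "healthy", ]
    h$lower <= 2540 && 2540 <= h$upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("NPDE boundary ranks follow the closed-form percentile", {
  # one subject, one observation far below every simulated replicate
  spec <- study_spec(n_per_group = 2)
  coh <- generate_cohort(spec, seed = 71)
  ds <- generate_study_dataset(coh, theta_reference(), spec, seed = 72)
  one <- ds[ds$ID == 1 & (ds$EVID == 1 | ds$TIME == 24), ]
  one$DV[one$EVID == 0] <- 1e-6   # essentially zero concentration
  res <- npde(one, theta_reference(), n_sim = 100, seed = 73)
  expect_equal(res$scores$npde, stats::qnorm(1 / 200), tolerance = 1e-9)
  expect_error(npde(one, n_sim = 20), ">= 50")
})

test_that("NPDE is self-consistent under the true model and flags a wrong one", {
  spec <- study_spec(n_per_group = 8)
  coh <- generate_cohort(spec, seed = 81)
  ds <- generate_study_dataset(coh, theta_reference(), spec, seed = 82)
  res <- npde(ds, theta_reference(), n_sim = 400, seed = 83)
  expect_lt(abs(res$mean), 0.15)
  expect_gt(res$variance, 0.75)
  expect_lt(res$variance, 1.25)
  # halving clearance in the evaluation model must be rejected
  th_bad <- theta_table(
    cl_healthy = 2540 / 2, cl_mild = 1550 / 2, cl_moderate = 1326 / 2,
    vc = 51400, q_healthy = 33678, q_mild = 38800, q_moderate = 63554,
    vp = 410000, ra = 0.653, gam1 = 4.57, kamax = 0.86, bmi_vp = 0.058,
    omega = theta_reference()$omega, sigma = 0.1788)
  bad <- npde(ds, th_bad, n_sim = 200, seed = 84)
  expect_lt(bad$p_global, 0.01)
})

test_that("tidiers expose fit results as tibbles", {
  ds <- make_iv_dataset(cl = rep(c(2540, 1550, 1326), each = 5),
                        group = rep(c("healthy", "mild", "moderate"), each = 5),
                        sigma = 0.1, seed = 91)
  fits <- fit_dataset(ds, n_starts = 1, seed = 92)
  ts <- two_stage_population(fits)
  expect_s3_class(tidy(ts), "tbl_df")
  expect_equal(nrow(glance(ts)), 1)
  expect_true(all(c("parameter", "group", "estimate", "omega") %in%
                    names(tidy(ts))))
})
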