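## hand-rolled single-row dataset in the shape fit_* expect
mk_surv_data <- function(time, status, trt, w = rep(1, length(time)),
                         id = sprintf("p%03d", seq_along(time))) {
  d <- data.frame(person_id = id,
                  strategy = ifelse(trt == 1, "tibolone", "non_initiator"),
                  initiator = trt == 1, sw = w,
                  time_composite_cvd = time,
                  status_composite_cvd = status,
                  stringsAsFactors = FALSE)
  attr(d, "contrast") <- "tibolone"
  d
}

test_that("two identical arms give a hazard ratio of exactly 1", {
  time <- c(50, 120, 300, 500, 730, 730)
  status <- c("event", "event", "event", "admin_censored", "admin_censored",
              "event")
  d <- mk_surv_data(c(time, time), rep(status, 2),
                    rep(c(1, 0), each = length(time)))
  est <- fit_cause_specific(d, "composite_cvd", "itt")
  expect_equal(est$log_hr, 0, tolerance = 1e-8)
  expect_equal(est$hr, 1, tolerance = 1e-8)
  expect_equal(est$ci95[1] <= 1 && est$ci95[2] >= 1, TRUE)
})

test_that("the fitted log hazard ratio maximises the weighted Efron partial likelihood", {
  set.seed(71)
  for (i in 1:6) {
    d0 <- random_small_cox_data()
    d <- mk_surv_data(d0$time,
                      ifelse(d0$status == 1, "event", "admin_censored"),
                      d0$z, d0$w)
    est <- fit_cause_specific(d, "composite_cvd", "itt")
    oracle <- brute_force_loghr(d0$time, d0$status, d0$z, d0$w)
    expect_lt(abs(est$log_hr - oracle), 1e-6)
  }
})

test_that("zero events in an arm is flagged inestimable, not an estimate", {
  d <- mk_surv_data(c(100, 200, 730, 730), c("event", "event",
                                             "admin_censored",
                                             "admin_censored"),
                    c(0, 0, 1, 1))
  est <- fit_cause_specific(d, "composite_cvd", "itt")
  expect_true(est$inestimable)
  expect_true(is.na(est$hr))
})

test_that("without competing events Fine-Gray coincides with the cause-specific model", {
  set.seed(73)
  n <- 120
  d <- mk_surv_data(round(rexp(n, 1 / 400)) + 1,
                    sample(c("event", "admin_censored"), n, TRUE),
                    rbinom(n, 1, 0.5), runif(n, 0.5, 2))
  cs <- fit_cause_specific(d, "composite_cvd", "itt")
  fg <- fit_fine_gray(d, "composite_cvd", "itt")
  expect_equal(fg$log_hr, cs$log_hr, tolerance = 1e-6)
})

test_that("the Fine-Gray path agrees with an independent subdistribution implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(79)
  n <- 3000
  time <- rexp(n, 1 / 300) + runif(n)     # continuous: no ties
  fstat <- sample(c("censor", "event", "competing_event"), n, TRUE,
                  prob = c(0.3, 0.4, 0.3))
  trt <- rbinom(n, 1, 0.5)
  d <- mk_surv_data(time, ifelse(fstat == "censor", "admin_censored", fstat),
                    trt)
  fg <- fit_fine_gray(d, "composite_cvd", "itt")
  crr_fit <- cmprsk::crr(time, match(fstat, c("censor", "event",
                                              "competing_event")) - 1,
                         cov1 = matrix(trt, ncol = 1), failcode = 1,
                         cencode = 0)
  expect_equal(fg$log_hr, unname(crr_fit$coef), tolerance = 1e-3)
})

test_that("an 8-subject dataset with one competing event matches the hand-expanded risk set", {
  ## all censoring falls at the administrative end (day 8), after every
  ## event, so the censoring Kaplan-Meier is 1 on the event range and the
  ## competing subject carries census weight 1 in every later risk set
  time <- c(1, 8, 3, 4, 5, 8, 7, 8)
  status <- c("event", "admin_censored", "competing_event", "event",
              "event", "admin_censored", "event", "admin_censored")
  trt <- c(1, 1, 1, 0, 0, 0, 1, 0)
  d <- mk_surv_data(time, status, trt)
  fg <- fit_fine_gray(d, "composite_cvd", "itt")
  ## hand expansion: the subdistribution partial likelihood equals a plain
  ## partial likelihood in which subject 3 remains at risk to the end
  fake_time <- time
  fake_time[3] <- 8.5            # keep the competing subject at risk
  fake_status <- as.integer(status == "event")
  oracle <- brute_force_loghr(fake_time, fake_status, trt)
  expect_equal(fg$log_hr, oracle, tolerance = 1e-6)
})

test_that("Fine-Gray attenuates toward the null when treatment raises competing mortality", {
  mix <- setNames(rep(0, 7), mhtemulate:::INITIATOR_STRATEGIES)
  mix["tibolone"] <- 1
  sc <- quick_scenario(
    n_women = 25000L, study_end = as.Date("2010-01-01"),
    monthly_init_prob = 0.3, strategy_mix = mix,
    baseline_rates = c(ihd = 18, cerebral_infarction = 7, vte = 12),
    competing_death_rate = 40,
    true_hr = list(tibolone = c(composite_cvd = 1, death = 4)),
    confounding_strength = numeric(), frac_prior_mht = 0, seed = 83L)
  out <- quick_person_trials(sc, outcomes = "composite_cvd")
  w <- fit_iptw(out$person_trials, "tibolone")
  cs <- fit_cause_specific(w, "composite_cvd", "itt")
  fg <- fit_fine_gray(w, "composite_cvd", "itt")
  expect_lt(fg$log_hr, cs$log_hr)      # total effect pulled down by deaths
  expect_equal(cs$log_hr, 0, tolerance = 0.2)   # direct effect is null
  expect_lt(fg$log_hr, -0.1)
})

test_that("hazard ratios are invariant to a uniform rescaling of time", {
  set.seed(89)
  n <- 150
  time <- rexp(n, 1 / 300) + runif(n)
  status <- sample(c("event", "admin_censored"), n, TRUE)
  d <- mk_surv_data(time, status, rbinom(n, 1, 0.5))
  est1 <- fit_cause_specific(d, "composite_cvd", "itt")
  d$time_composite_cvd <- d$time_composite_cvd / 7
  est2 <- fit_cause_specific(d, "composite_cvd", "itt")
  expect_equal(est2$log_hr, est1$log_hr, tolerance = 1e-10)
})

test_that("cluster-robust intervals widen on stacked data with repeated women", {
  sc <- quick_scenario(n_women = 2500L, monthly_init_prob = 0.04,
                       baseline_rates = c(ihd = 30, cerebral_infarction = 12,
                                          vte = 20), seed = 91L)
  out <- quick_person_trials(sc, outcomes = "composite_cvd")
  w <- fit_iptw(out$person_trials, "oral_combined_continuous")
  est <- fit_cause_specific(w, "composite_cvd", "itt")
  naive <- survival::coxph(
    survival::Surv(time_composite_cvd, status_composite_cvd == "event") ~
      initiator, data = w, weights = sw, ties = "efron")
  expect_gte(est$se_robust, sqrt(naive$var[1, 1]) * 0.999)
})

test_that("adjusted incidence starts at zero, is null for identical arms, and scales of weights cancel in rates", {
  time <- c(50, 120, 300, 500, 730, 730)
  status <- c("event", "event", "competing_event", "death",
              "admin_censored", "admin_censored")
  d <- mk_surv_data(c(time, time), rep(status, 2),
                    rep(c(1, 0), each = length(time)))
  inc <- adjusted_incidence(d, "composite_cvd")
  expect_equal(unname(inc$cif[, 1]), c(0, 0))
  expect_equal(unname(inc$risk_difference_1y), 0, tolerance = 1e-12)
  expect_equal(inc$cif["tibolone", ], inc$cif["non_initiator", ])
  r1 <- adjusted_rates(d, "composite_cvd")
  d2 <- d
  d2$sw <- d2$sw * 2
  r2 <- adjusted_rates(d2, "composite_cvd")
  expect_equal(r2$rate_per_1000py, r1$rate_per_1000py)
})

test_that("adjusted rates recover a textbook unit case", {
  n <- 500
  d <- mk_surv_data(rep(730, 2 * n),
                    c("event", rep("admin_censored", 2 * n - 1)),
                    rep(c(1, 0), each = n))
  r <- adjusted_rates(d, "composite_cvd")
  ## one event in ~1000 person-years in the treated arm
  treated <- r[r$arm == "tibolone", ]
  expect_equal(treated$person_years, n * 730 / 365.25)
  expect_equal(treated$rate_per_1000py, 1, tolerance = 0.01)
})
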