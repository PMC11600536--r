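test_that("generation is deterministic under a fixed seed and distinct across seeds", {
  sc <- quick_scenario(n_women = 300L, seed = 5L)
  r1 <- simulate_registry(sc)
  r2 <- simulate_registry(sc)
  for (tab in c("persons", "dispensations", "diagnoses", "procedures"))
    expect_identical(r1[[tab]], r2[[tab]])
  r3 <- simulate_registry(quick_scenario(n_women = 300L, seed = 6L))
  expect_false(identical(r1$dispensations, r3$dispensations))
})

test_that("covariate marginals match their targets (diabetes medication among non-initiators)", {
  sc <- quick_scenario(n_women = 50000L, monthly_init_prob = 0.001,
                       seed = 31L)
  pop <- simulate_population(sc)
  gt <- attr(pop, "ground_truth")
  expect_equal(mean(gt$med_diabetes), 0.078, tolerance = 0.01 / 0.078)
  expect_true(abs(mean(gt$med_diabetes) - 0.078) < 0.01)
  ## age span covers the 50-58 window with margin at both ends
  expect_lt(min(gt$age_at_start), 48.5)
  expect_gt(max(gt$age_at_start), 59.5)
})

test_that("zero confounding makes initiation independent of the covariates", {
  ## stratified independence check over repeated seeds
  p <- numeric(10)
  for (i in seq_len(10)) {
    sc <- quick_scenario(n_women = 20000L, monthly_init_prob = 0.01,
                         confounding_strength = numeric(), seed = 100L + i)
    disp <- simulate_dispensations(simulate_population(sc), sc)
    gt <- attr(disp, "ground_truth")
    init <- gt$strategy != "non_initiator"
    p[i] <- stats::chisq.test(table(init, gt$med_heart_disease))$p.value
  }
  expect_gte(sum(p > 0.05), 8L)
})

test_that("initiators refill until a geometric stop with the closed-form mean", {
  sc <- quick_scenario(n_women = 12000L, monthly_init_prob = 0.5,
                       study_end = as.Date("2010-01-01"),
                       monthly_stop_prob = 0.1, package_sizes = 28L,
                       frac_prior_mht = 0, seed = 17L)
  disp <- simulate_dispensations(simulate_population(sc), sc)
  gt <- attr(disp, "ground_truth")
  init <- gt$strategy != "non_initiator"
  ## fills redeemed within two years of initiation
  q <- (1 - 0.1)^(28 / 30)
  m <- floor(730 / 28) + 1L
  expected <- (1 - q^m) / (1 - q)
  counted <- vapply(which(init), function(i) {
    min(gt$n_mht_fills[i], m)
  }, numeric(1))
  expect_equal(mean(counted), expected, tolerance = 0.05)
})

test_that("monthly_stop_prob = 1 gives exactly one fill per initiator", {
  sc <- quick_scenario(n_women = 1000L, monthly_init_prob = 0.3,
                       monthly_stop_prob = 1, frac_prior_mht = 0, seed = 8L)
  disp <- simulate_dispensations(simulate_population(sc), sc)
  gt <- attr(disp, "ground_truth")
  expect_true(all(gt$n_mht_fills[gt$strategy != "non_initiator"] == 1L))
})

test_that("self-combined sequential pairs fall on the >7 side of the dose ratio", {
  mix <- setNames(rep(0, 7), mhtemulate:::INITIATOR_STRATEGIES)
  mix["oral_combined_sequential"] <- 1
  sc <- quick_scenario(n_women = 2000L, monthly_init_prob = 0.2,
                       strategy_mix = mix, fixed_product_frac = 0,
                       frac_prior_mht = 0, seed = 12L)
  disp <- simulate_dispensations(simulate_population(sc), sc)
  d <- disp[disp$hormone_content %in% c("oestrogen_only",
                                        "progestogen_only"), ]
  by_day <- split(d, paste(d$person_id, d$dispense_date))
  ratios <- vapply(by_day, function(g)
    sum(g$oestrogen_dose) / sum(g$progestogen_dose), numeric(1))
  expect_true(all(ratios > 7))
})

test_that("with no treatment effect the pooled composite rate recovers its generative value", {
  marg <- mhtemulate:::default_covariate_marginals()
  marg$med <- c(hypertension = 0, heart_disease = 0, diabetes = 0)
  sc <- simulation_scenario(
    n_women = 150000L, study_start = as.Date("2010-01-01"),
    study_end = as.Date("2010-12-01"), monthly_init_prob = 0,
    confounding_strength = numeric(), covariate_marginals = marg,
    frac_prior_mht = 0, frac_prior_disease = 0, frac_procedure = 0,
    fatal_event_frac = 0, seed = 19L)
  reg <- simulate_registry(sc)
  cb <- default_codebook()
  dx <- reg$diagnoses
  comp <- dx[code_match(dx$icd10_code, cb$outcome_codes$composite_cvd), ]
  first <- tapply(as.integer(comp$event_date), comp$person_id, min)
  entry <- as.integer(sc$study_start)
  horizon <- as.integer(sc$study_end) + 730L
  p <- reg$persons
  stop_day <- pmin(as.integer(p$death_date), as.integer(p$emigration_date),
                   horizon, na.rm = TRUE)
  ev_day <- rep(NA_integer_, nrow(p))
  j <- match(names(first), p$person_id)
  ev_day[j] <- as.integer(first)
  at_risk_end <- pmin(stop_day, ev_day, na.rm = TRUE)
  py <- sum(at_risk_end - entry) / 365.25
  rate <- sum(!is.na(ev_day) & ev_day <= stop_day) / py * 1000
  expect_gt(py, 4e5)
  expect_equal(rate, 3.56, tolerance = 0.3 / 3.56)
})

test_that("a null scenario without confounding gives a crude initiator rate ratio near 1", {
  sc <- quick_scenario(n_women = 30000L, monthly_init_prob = 0.15,
                       study_end = as.Date("2010-02-01"),
                       baseline_rates = c(ihd = 36, cerebral_infarction = 14,
                                          vte = 25),
                       confounding_strength = numeric(),
                       frac_prior_mht = 0, seed = 44L)
  out <- quick_person_trials(sc, outcomes = "composite_cvd")
  pt <- out$person_trials
  ev <- pt$status_composite_cvd == "event"
  rate <- tapply(ev, pt$initiator, sum) /
    tapply(pt$time_composite_cvd, pt$initiator, sum)
  rr <- rate[["TRUE"]] / rate[["FALSE"]]
  expect_equal(unname(rr), 1, tolerance = 0.25)
})

test_that("a generative hazard ratio shows up in exposed person-time at the right magnitude", {
  mix <- setNames(rep(0, 7), mhtemulate:::INITIATOR_STRATEGIES)
  mix["tibolone"] <- 1
  sc <- quick_scenario(n_women = 60000L, monthly_init_prob = 0.25,
                       study_end = as.Date("2010-01-01"),
                       strategy_mix = mix,
                       true_hr = list(tibolone = c(composite_cvd = 2)),
                       baseline_rates = c(ihd = 36, cerebral_infarction = 14,
                                          vte = 25),
                       confounding_strength = numeric(),
                       frac_prior_mht = 0, effect_mode = "itt", seed = 27L)
  reg <- simulate_registry(sc)
  gt <- attr(reg, "ground_truth")
  ## empirical rates on the latent first-event times, by exposure flag
  t_comp <- pmin(gt$t_ihd, gt$t_cerebral_infarction, na.rm = TRUE)
  horizon <- as.integer(sc$study_end) + 730L - as.integer(sc$study_start)
  stop_t <- pmin(ifelse(is.na(t_comp), horizon, t_comp),
                 ifelse(is.na(gt$t_death), horizon, gt$t_death), horizon)
  exposed <- gt$strategy != "non_initiator"
  ev <- !is.na(t_comp) & t_comp <= stop_t
  ## restrict exposed person-time to the effect window
  es <- ifelse(is.na(gt$exposure_start), Inf, gt$exposure_start)
  t_in <- pmin(stop_t, gt$exposure_end, na.rm = TRUE) - pmin(es, stop_t)
  rate_exp <- sum(ev[exposed] & t_comp[exposed] >= es[exposed] &
                    t_comp[exposed] <= gt$exposure_end[exposed]) /
    sum(pmax(t_in[exposed], 0))
  rate_un <- sum(ev[!exposed]) / sum(stop_t[!exposed])
  expect_equal(rate_exp / rate_un, 2, tolerance = 0.15)
})

test_that("every woman has at most one first-event record per cause and none after death", {
  sc <- quick_scenario(n_women = 3000L, seed = 3L,
                       baseline_rates = c(ihd = 40, cerebral_infarction = 20,
                                          vte = 30))
  reg <- simulate_registry(sc)
  cb <- default_codebook()
  cats <- mhtemulate:::atomic_code_sets(cb)
  ## incident records only: the pre-study exclusion histories are a
  ## separate stream and may reuse outcome rubrics
  dx <- reg$diagnoses[reg$diagnoses$event_date >= sc$study_start, ]
  for (cat in names(cats)) {
    sub <- dx[code_match(dx$icd10_code, cats[[cat]]), ]
    expect_false(anyDuplicated(sub$person_id) > 0)
  }
  term <- pmin(as.integer(reg$persons$death_date),
               as.integer(reg$persons$emigration_date), na.rm = TRUE)
  j <- match(dx$person_id, reg$persons$person_id)
  ok <- is.na(term[j]) | as.integer(dx$event_date) <= term[j]
  expect_true(all(ok))
})

test_that("non-informative stopping is independent of the censoring covariate", {
  sc <- quick_scenario(n_women = 20000L, monthly_init_prob = 0.2,
                       study_end = as.Date("2010-01-01"),
                       monthly_stop_prob = 0.15,
                       informative_censoring = FALSE, frac_prior_mht = 0,
                       seed = 52L)
  disp <- simulate_dispensations(simulate_population(sc), sc)
  gt <- attr(disp, "ground_truth")
  init <- gt$strategy != "non_initiator"
  few <- gt$n_mht_fills <= 3L
  tab <- table(few[init], gt$geo_region[init] == "urban")
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})
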