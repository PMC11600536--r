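test_that("stacked rows equal the per-trial eligible counts and respect the washout/assignment consistency", {
  sc <- quick_scenario(n_women = 1000L, monthly_init_prob = 0.05, seed = 33L)
  out <- quick_person_trials(sc, outcomes = "composite_cvd")
  per_trial <- table(out$eligibility$trial_index[out$eligibility$eligible])
  stacked <- table(out$person_trials$trial_index)
  expect_equal(as.integer(stacked), as.integer(per_trial))
  expect_equal(nrow(out$person_trials), sum(out$eligibility$eligible))
})

test_that("a never-initiating woman contributes one non-initiator row per eligible trial", {
  persons <- eligibility_fixture()$persons[8, ]
  reg <- new_registry(persons, mk_disp("zz")[0, ],
                      eligibility_fixture()$diagnoses[0, ],
                      eligibility_fixture()$procedures[0, ])
  trials <- make_trial_sequence(as.Date("2010-01-01"), as.Date("2011-12-01"))
  cb <- default_codebook()
  elig <- screen_trials(reg, cb, trials, keep = "eligible")
  asg <- assign_strategies(elig, reg, trials)
  pt <- build_person_trials(elig, asg, reg, cb, trials,
                            outcomes = "composite_cvd")
  expect_equal(nrow(pt), 24L)
  expect_true(all(pt$strategy == "non_initiator"))
})

test_that("an initiator in trial 3 has one initiator row and vanishes from the next trials", {
  persons <- eligibility_fixture()$persons[8, ]
  fill <- mk_disp("f08", as.Date("2010-03-10"))
  reg <- new_registry(persons, fill, eligibility_fixture()$diagnoses[0, ],
                      eligibility_fixture()$procedures[0, ])
  trials <- make_trial_sequence(as.Date("2010-01-01"), as.Date("2010-12-01"))
  cb <- default_codebook()
  elig <- screen_trials(reg, cb, trials, keep = "eligible")
  asg <- assign_strategies(elig, reg, trials)
  pt <- build_person_trials(elig, asg, reg, cb, trials,
                            outcomes = "composite_cvd")
  expect_equal(pt$trial_index, 1:3)
  expect_equal(pt$strategy, c("non_initiator", "non_initiator",
                              "oral_unopposed_oestrogen"))
})

test_that("outcome ascertainment follows the cause-specific conventions", {
  cb <- default_codebook()
  s <- as.Date("2010-01-01")
  dx <- function(code, day) data.frame(
    person_id = "w1", event_date = s + day, icd10_code = code,
    source = "patient_register", stringsAsFactors = FALSE)
  ## first post-baseline I21 at day 100, analysing ihd: an event
  r <- ascertain_outcome("w1", s, dx("I21", 100), cb, "ihd")
  expect_equal(r$time, 100L)
  expect_equal(r$status, "event")
  ## I63 at day 50 then I21 at day 60, analysing mi: competing at 50
  d2 <- rbind(dx("I63", 50), dx("I21", 60))
  r2 <- ascertain_outcome("w1", s, d2, cb, "mi")
  expect_equal(r2$time, 50L)
  expect_equal(r2$status, "competing_event")
  ## the same history, analysing cerebral infarction: the event
  r3 <- ascertain_outcome("w1", s, d2, cb, "cerebral_infarction")
  expect_equal(list(r3$time, r3$status), list(50L, "event"))
  ## MI never competes against the IHD analysis (MI is an IHD event)
  r4 <- ascertain_outcome("w1", s, d2, cb, "ihd")
  expect_equal(r4$status, "competing_event")  # the I63 at day 50 censors
  r5 <- ascertain_outcome("w1", s, dx("I22", 30), cb, "ihd")
  expect_equal(list(r5$time, r5$status), list(30L, "event"))
  ## no events, alive, present: administrative censoring at day 730
  r6 <- ascertain_outcome("w1", s, dx("I21", 100)[0, ], cb, "composite_cvd")
  expect_equal(list(r6$time, r6$status), list(730L, "admin_censored"))
  ## vte competition is a configuration switch
  r7 <- ascertain_outcome("w1", s, dx("I80", 40), cb, "ihd")
  expect_equal(r7$status, "competing_event")
  r8 <- ascertain_outcome("w1", s, dx("I80", 40), cb, "ihd",
                          vte_competes = FALSE)
  expect_equal(list(r8$time, r8$status), list(730L, "admin_censored"))
})

test_that("terminal states resolve in the documented priority at ties", {
  cb <- default_codebook()
  s <- as.Date("2010-01-01")
  d <- data.frame(person_id = "w1", event_date = s + 90, icd10_code = "I21",
                  source = "cause_of_death", stringsAsFactors = FALSE)
  ## fatal MI on day 90: the event wins over death on the same day
  r <- ascertain_outcome("w1", s, d, cb, "composite_cvd",
                         death_date = s + 90)
  expect_equal(list(r$time, r$status), list(90L, "event"))
  r2 <- ascertain_outcome("w1", s, d[0, ], cb, "composite_cvd",
                          death_date = s + 90, emigration_date = s + 90)
  expect_equal(r2$status, "death")
})

test_that("the composite event never postdates a component event", {
  sc <- quick_scenario(n_women = 1200L, seed = 61L,
                       baseline_rates = c(ihd = 40, cerebral_infarction = 16,
                                          vte = 28))
  pt <- quick_person_trials(sc)$person_trials
  for (oo in c("ihd", "mi", "cerebral_infarction")) {
    has <- pt[[paste0("status_", oo)]] == "event"
    expect_true(all(pt$time_composite_cvd[has] <=
                      pt[[paste0("time_", oo)]][has]))
  }
  ## every person-trial holds exactly one terminal state per outcome
  for (oo in OUTCOMES_ALL) {
    expect_true(all(pt[[paste0("status_", oo)]] %in%
                      mhtemulate:::FOLLOWUP_STATUSES))
    expect_true(all(pt[[paste0("time_", oo)]] > 0 &
                      pt[[paste0("time_", oo)]] <= 730))
  }
})

test_that("incidence trends: empty table, unit case, and flatness under a constant hazard", {
  cb <- default_codebook()
  n <- 10000L
  persons <- data.frame(
    person_id = sprintf("p%05d", 1:n),
    birth_date = as.Date("1955-06-01"),
    education = "high_school", region_of_birth = "Nordics",
    geo_region = "urban", first_registered = as.Date("1990-01-01"),
    death_date = as.Date(NA), emigration_date = as.Date(NA),
    stringsAsFactors = FALSE)
  empty <- data.frame(person_id = character(),
                      event_date = as.Date(character()),
                      icd10_code = character(), source = character())
  tr0 <- compute_incidence_trends(empty, persons, cb, 2010)
  expect_true(all(tr0[, startsWith(names(tr0), "rate_")] == 0))
  ## one first-ever event among 10 000 woman-years: rate 1 per 10 000
  one <- data.frame(person_id = "p00001", event_date = as.Date("2010-06-01"),
                    icd10_code = "I21", source = "patient_register")
  tr1 <- compute_incidence_trends(one, persons, cb, 2010)
  expect_equal(tr1$person_years, n, tolerance = 0.01)
  expect_equal(tr1$rate_ihd, 1, tolerance = 0.02)
  expect_equal(tr1$rate_mi, 1, tolerance = 0.02)
  expect_equal(tr1$rate_vte, 0)
  ## constant-hazard synthetic data shows a flat trend
  sc <- quick_scenario(n_women = 40000L, monthly_init_prob = 0,
                       study_end = as.Date("2012-12-01"),
                       confounding_strength = numeric(), seed = 77L)
  reg <- simulate_registry(sc)
  tr <- compute_incidence_trends(reg$diagnoses, reg$persons, cb,
                                 2010:2012, outcomes = "composite_cvd")
  rates <- tr$rate_composite_cvd
  expect_true(all(abs(rates - mean(rates)) / mean(rates) < 0.3))
})
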