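test_that("the monthly trial sequence spans the study window inclusively", {
  expect_equal(nrow(make_trial_sequence(as.Date("2007-07-01"),
                                        as.Date("2018-12-01"))), 138L)
  expect_equal(nrow(make_trial_sequence(as.Date("2007-07-01"),
                                        as.Date("2007-07-01"))), 1L)
  expect_equal(nrow(make_trial_sequence(as.Date("2010-01-01"),
                                        as.Date("2011-12-01"))), 24L)
  tr <- make_trial_sequence(as.Date("2010-11-01"), as.Date("2011-02-01"))
  expect_equal(tr$start_date,
               as.Date(c("2010-11-01", "2010-12-01", "2011-01-01",
                         "2011-02-01")))
  expect_error(make_trial_sequence(as.Date("2010-01-15"),
                                   as.Date("2010-06-01")), "month")
})

test_that("the hand-audited 12-woman fixture yields exactly 5 eligible with the right failure labels", {
  reg <- eligibility_fixture()
  trial <- make_trial_sequence(as.Date("2010-06-01"), as.Date("2010-06-01"))
  dec <- screen_trial(reg, default_codebook(), trial[1, ])
  expect_equal(sum(dec$eligible), 5L)
  fails <- setNames(dec$failed_criteria, dec$person_id)
  expect_equal(fails[["f01"]], "age")
  expect_equal(fails[["f02"]], "washout")
  expect_equal(fails[["f03"]], "prior_disease")
  expect_equal(fails[["f04"]], "procedure")
  expect_equal(fails[["f05"]], "dead")
  expect_equal(fails[["f06"]], "emigrated")
  expect_equal(fails[["f07"]], "late_registration")
  expect_true(all(fails[sprintf("f%02d", 8:12)] == ""))
})

test_that("age is completed years at the trial start (birthday arithmetic)", {
  ## 49 years 11 months at start: ineligible; one month later: eligible
  reg <- eligibility_fixture()
  p <- reg$persons[reg$persons$person_id == "f01", ]
  expect_equal(completed_years(p$birth_date, as.Date("2010-06-01")), 49L)
  expect_equal(completed_years(p$birth_date, as.Date("2010-07-01")), 50L)
  tr <- make_trial_sequence(as.Date("2010-06-01"), as.Date("2010-07-01"))
  dec <- screen_trials(reg, default_codebook(), tr)
  d1 <- dec[dec$person_id == "f01", ]
  expect_equal(d1$eligible, c(FALSE, TRUE))
})

test_that("a fill inside the washout blocks eligibility until it ages out of the window", {
  ## fill 600 days before the first trial start; 730-day washout
  persons <- eligibility_fixture()$persons[8, ]
  start <- as.Date("2010-06-01")
  reg <- new_registry(persons, mk_disp("f08", start - 600),
                      eligibility_fixture()$diagnoses[0, ],
                      eligibility_fixture()$procedures[0, ])
  tr <- make_trial_sequence(start, as.Date("2010-11-01"))
  dec <- screen_trials(reg, default_codebook(), tr)
  d <- dec[dec$person_id == "f08", ]
  expect_false(d$eligible[1])             # 600 < 730: inside washout
  expect_true(d$eligible[6])              # 5 months later: 753 days ago
})

test_that("washout is monotone: lengthening it never makes an ineligible woman eligible", {
  sc <- quick_scenario(n_women = 400L, monthly_init_prob = 0.05,
                       frac_prior_mht = 0.3, seed = 9L)
  reg <- simulate_registry(sc)
  cb <- default_codebook()
  tr730 <- make_trial_sequence(sc$study_start, sc$study_end, 730L)
  tr2190 <- make_trial_sequence(sc$study_start, sc$study_end, 2190L)
  d730 <- screen_trials(reg, cb, tr730)
  d2190 <- screen_trials(reg, cb, tr2190)
  expect_false(any(!d730$eligible & d2190$eligible))
  expect_lte(sum(d2190$eligible), sum(d730$eligible))
})

test_that("an initiator is ineligible for the following 24 trials under the 730-day washout", {
  persons <- eligibility_fixture()$persons[8, ]
  fill <- mk_disp("f08", as.Date("2010-01-15"))
  reg <- new_registry(persons, fill, eligibility_fixture()$diagnoses[0, ],
                      eligibility_fixture()$procedures[0, ])
  tr <- make_trial_sequence(as.Date("2010-01-01"), as.Date("2012-03-01"))
  dec <- screen_trials(reg, default_codebook(), tr)
  d <- dec[dec$person_id == "f08", ]
  expect_true(d$eligible[1])                   # the initiation trial itself
  expect_true(all(!d$eligible[2:25]))          # the next 24 trials
  expect_true(d$eligible[26])                  # 2012-02-01: fill aged out
})

test_that("unilateral oophorectomy excludes only on two distinct dates", {
  persons <- rbind(eligibility_fixture()$persons[8, ],
                   transform(eligibility_fixture()$persons[9, ]))
  proc <- data.frame(
    person_id = c("f08", "f09", "f09"),
    event_date = as.Date(c("2000-01-01", "2000-01-01", "2003-05-01")),
    procedure = "unilateral_oophorectomy", stringsAsFactors = FALSE)
  reg <- new_registry(persons, mk_disp("zz")[0, ],
                      eligibility_fixture()$diagnoses[0, ], proc)
  tr <- make_trial_sequence(as.Date("2010-06-01"), as.Date("2010-06-01"))
  dec <- screen_trial(reg, default_codebook(), tr[1, ])
  expect_true(dec$eligible[dec$person_id == "f08"])   # once: not excluded
  expect_false(dec$eligible[dec$person_id == "f09"])  # twice: excluded
})

test_that("screening is idempotent and order-independent over persons", {
  reg <- eligibility_fixture()
  tr <- make_trial_sequence(as.Date("2010-06-01"), as.Date("2010-06-01"))
  d1 <- screen_trial(reg, default_codebook(), tr[1, ])
  reg2 <- reg
  perm <- c(5, 3, 11, 1, 8, 2, 12, 7, 10, 4, 6, 9)
  reg2$persons <- reg2$persons[perm, ]
  d2 <- screen_trial(reg2, default_codebook(), tr[1, ])
  d2 <- d2[match(d1$person_id, d2$person_id), ]
  expect_equal(d2$eligible, d1$eligible)
  expect_equal(d2$failed_criteria, d1$failed_criteria)
})
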