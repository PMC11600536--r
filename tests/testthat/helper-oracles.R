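## Independent oracles and hand-built fixtures shared across the suite.

## ---- brute-force weighted Efron partial likelihood --------------------
## Written directly from the likelihood definition; kept independent of the
## coxph-based fitting path it checks.
efron_loglik <- function(beta, time, status, z, w) {
  eta <- beta * z
  r <- w * exp(eta)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(r[R])
    sD <- sum(r[D])
    wbar <- sum(w[D]) / d
    ll <- ll + sum(w[D] * eta[D]) -
      sum(wbar * log(sR - (0:(d - 1)) / d * sD))
  }
  ll
}

brute_force_loghr <- function(time, status, z, w = rep(1, length(time))) {
  stats::optimize(function(b) -efron_loglik(b, time, status, z, w),
                  c(-8, 8), tol = 1e-12)$minimum
}

## random small survival datasets with a finite, interior partial-MLE
random_small_cox_data <- function(n_max = 10L) {
  repeat {
    n <- sample(4:n_max, 1L)
    d <- data.frame(time = sample(1:8, n, replace = TRUE),
                    status = stats::rbinom(n, 1L, 0.7),
                    z = stats::rbinom(n, 1L, 0.5),
                    w = round(stats::runif(n, 0.5, 2.5), 2))
    if (sum(d$status[d$z == 1]) == 0 || sum(d$status[d$z == 0]) == 0) next
    b <- brute_force_loghr(d$time, d$status, d$z, d$w)
    if (abs(b) < 4) return(d)
  }
}

## ---- dispensation row constructor -------------------------------------
mk_disp <- function(person_id = "w1", date = as.Date("2010-06-10"),
                    hormone_content = "oestrogen_only", route = "oral",
                    oestrogen_dose = 2, progestogen_dose = 0,
                    n_packages = 1L, ddd_per_package = 28L,
                    atc_code = "G03CA03") {
  data.frame(person_id = person_id, dispense_date = as.Date(date),
             atc_code = atc_code, route = route,
             hormone_content = hormone_content,
             oestrogen_dose = oestrogen_dose,
             progestogen_dose = progestogen_dose,
             n_packages = as.integer(n_packages),
             ddd_per_package = as.integer(ddd_per_package),
             stringsAsFactors = FALSE)
}

## ---- 16-case strategy decision table ----------------------------------
## Hand-audited truth table covering every classification branch,
## including the ratio-exactly-7 tie.
strategy_decision_table <- function() {
  oe <- function(route = "oral", e = 2) mk_disp(route = route,
                                                oestrogen_dose = e)
  pg <- function(route = "oral", p = 0.5)
    mk_disp(hormone_content = "progestogen_only", route = route,
            oestrogen_dose = 0, progestogen_dose = p, atc_code = "G03DC02")
  tib <- mk_disp(hormone_content = "tibolone", oestrogen_dose = 0,
                 atc_code = "G03CX01")
  lng <- mk_disp(hormone_content = "lng_ius", route = "local",
                 oestrogen_dose = 0, progestogen_dose = 0.02,
                 atc_code = "G02BA03")
  fx <- function(hc, route = "oral")
    mk_disp(hormone_content = hc, route = route, oestrogen_dose = 2,
            progestogen_dose = 1, atc_code = "G03FA01")
  list(
    list(d = mk_disp()[0, ], truth = "non_initiator"),
    list(d = tib, truth = "tibolone"),
    list(d = rbind(tib, oe(), pg()), truth = "tibolone"),
    list(d = rbind(oe("transdermal", 0.05), pg()),
         truth = "transdermal_combined"),
    list(d = rbind(oe("transdermal", 0.05), pg("transdermal")),
         truth = "transdermal_combined"),
    list(d = rbind(oe("transdermal", 0.05), lng),
         truth = "transdermal_combined"),
    list(d = fx("fixed_combined_continuous", "transdermal"),
         truth = "transdermal_combined"),
    list(d = oe("transdermal", 0.05),
         truth = "transdermal_unopposed_oestrogen"),
    list(d = rbind(oe("transdermal", 0.05), oe()),
         truth = "transdermal_unopposed_oestrogen"),
    list(d = rbind(oe(), lng), truth = "oral_oestrogen_lng_ius"),
    list(d = fx("fixed_combined_continuous"),
         truth = "oral_combined_continuous"),
    list(d = fx("fixed_combined_sequential"),
         truth = "oral_combined_sequential"),
    list(d = rbind(oe(e = 2), pg(p = 0.5)),       # ratio 4 < 7
         truth = "oral_combined_continuous"),
    list(d = rbind(oe(e = 2), pg(p = 0.25)),      # ratio 8 > 7
         truth = "oral_combined_sequential"),
    list(d = rbind(oe(e = 3.5), pg(p = 0.5)),     # ratio exactly 7: tie
         truth = "oral_combined_continuous"),
    list(d = oe(), truth = "oral_unopposed_oestrogen")
  )
}

## ---- hand-audited eligibility fixture ---------------------------------
## 12 women: one violation of each of the 7 criteria, plus 5 clean records.
## Trial month June 2010, washout 730 days.
eligibility_fixture <- function() {
  clean_birth <- as.Date("1955-06-15")          # aged 54 at 2010-06-01
  persons <- data.frame(
    person_id = sprintf("f%02d", 1:12),
    birth_date = c(as.Date("1960-07-01"),       # f01 aged 49y11m: age
                   rep(clean_birth, 11)),
    education = "high_school", region_of_birth = "Nordics",
    geo_region = "urban",
    first_registered = c(rep(as.Date("1995-01-01"), 6),
                         as.Date("2006-05-01"), # f07 late registration
                         rep(as.Date("1995-01-01"), 5)),
    death_date = as.Date(c(rep(NA, 4), "2010-05-01", rep(NA, 7))),  # f05
    emigration_date = as.Date(c(rep(NA, 5), "2010-01-01", rep(NA, 6))), # f06
    stringsAsFactors = FALSE)
  dispensations <- mk_disp("f02", as.Date("2009-10-01"))  # 243d: washout
  diagnoses <- data.frame(person_id = "f03",
                          event_date = as.Date("2005-03-01"),
                          icd10_code = "I219", source = "patient_register",
                          stringsAsFactors = FALSE)      # prior disease
  procedures <- data.frame(person_id = "f04",
                           event_date = as.Date("2000-01-01"),
                           procedure = "hysterectomy",
                           stringsAsFactors = FALSE)
  new_registry(persons, dispensations, diagnoses, procedures)
}

## ---- small synthetic scenario shortcut --------------------------------
quick_scenario <- function(...) {
  args <- list(...)
  defaults <- list(n_women = 2000L, study_start = as.Date("2010-01-01"),
                   study_end = as.Date("2010-06-01"),
                   monthly_init_prob = 0.03,
                   baseline_rates = c(ihd = 12, cerebral_infarction = 5,
                                      vte = 9),
                   seed = 42L)
  do.call(simulation_scenario, utils::modifyList(defaults, args))
}

## registry + stacked person-trials in one call
quick_person_trials <- function(sc, outcomes = OUTCOMES_ALL) {
  reg <- simulate_registry(sc)
  trials <- make_trial_sequence(sc$study_start, sc$study_end)
  cb <- default_codebook()
  elig <- screen_trials(reg, cb, trials, keep = "eligible")
  asg <- assign_strategies(elig, reg, trials)
  pt <- build_person_trials(elig, asg, reg, cb, trials, outcomes = outcomes)
  list(registry = reg, trials = trials, codebook = cb,
       eligibility = elig, assignments = asg, person_trials = pt)
}

OUTCOMES_ALL <- c("composite_cvd", "ihd", "mi", "cerebral_infarction", "vte")
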