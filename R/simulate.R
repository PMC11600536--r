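## Synthetic linked registries with known generative structure: confounded
## treatment initiation, strategy-specific cause-specific exponential
## hazards with known true hazard ratios, adherence/discontinuation
## processes (optionally informative), and competing death/emigration.
## Closed-form exponential hazards are used so that oracle checks (rates,
## geometric refill counts, risk differences) have analytic answers.

SIM_OUTCOME_CAUSES <- c("ihd", "cerebral_infarction", "vte")

default_covariate_marginals <- function() {
  list(
    education = c(elementary = 0.1280, high_school = 0.4739,
                  higher_education = 0.3830, research = 0.0106,
                  unknown = 0.0045),
    region_of_birth = c(Nordics = 0.8684, Africa = 0.0091, Asia = 0.0443,
                        Europe_non_Nordic = 0.0657, North_America = 0.0034,
                        Oceania = 0.0003, South_America = 0.0088),
    geo_region = c(urban = 0.3230, semi_urban = 0.1050,
                   semi_rural = 0.4140, rural = 0.1590),
    med = c(hypertension = 0.270, heart_disease = 0.107, diabetes = 0.078)
  )
}

default_strategy_mix <- function() {
  c(oral_combined_continuous = 0.3687, oral_combined_sequential = 0.2030,
    oral_unopposed_oestrogen = 0.0577, oral_oestrogen_lng_ius = 0.0555,
    tibolone = 0.0780, transdermal_combined = 0.1575,
    transdermal_unopposed_oestrogen = 0.0796)
}

#' Define a simulation scenario
#'
#' The scenario fixes every knob of the synthetic registry generator:
#' population size and study window, baseline cause-specific event rates
#' (events per 1000 person-years; the defaults partition the published
#' pooled non-initiator composite rate of 3.56 per 1000 person-years across
#' ischaemic heart disease and cerebral infarction by their observed event
#' shares, with venous thromboembolism alongside), the generative treatment
#' effects (`true_hr`, multiplicative on the cause-specific hazard), the
#' initiator strategy mix (defaulting to the published distribution, with
#' oral combined continuous therapy above a third of initiations),
#' confounding strengths (log-odds effect on initiation and, identically,
#' log-hazard effect on the outcome), the monthly initiation and
#' discontinuation probabilities, informative-censoring controls, and
#' competing death/emigration rates.
#'
#' @param n_women number of women
#' @param study_start,study_end first and last trial months (month-aligned)
#' @param followup_days per-trial follow-up (730)
#' @param baseline_rates named vector, events per 1000 person-years for
#'   `ihd`, `cerebral_infarction`, `vte`
#' @param mi_fraction share of ihd events coded as myocardial infarction
#'   (I21/I22)
#' @param true_hr named list: `true_hr[[strategy]]` is a named vector of
#'   hazard ratios by outcome (`composite_cvd` applies to both arterial
#'   causes unless a cause is given explicitly; `death` scales the
#'   competing death hazard); unlisted entries default to 1
#' @param strategy_mix probability simplex over the seven initiator
#'   strategies
#' @param monthly_init_prob baseline per-month initiation probability while
#'   aged 50-58 (logit scale intercept)
#' @param monthly_stop_prob baseline per-month probability of stopping
#'   refills after initiation
#' @param confounding_strength named vector of log-odds effects on
#'   initiation that equally act as log-hazard effects on the outcome;
#'   supported names: `med_hypertension`, `med_heart_disease`,
#'   `med_diabetes`, `urban`, `rural`, `elementary_education`,
#'   `higher_education`, `non_nordic`, `age`
#' @param hazard_only_strength like `confounding_strength` but acting on
#'   the outcome hazard only (a risk factor that does not influence
#'   prescribing)
#' @param informative_censoring if `TRUE`, the monthly stop probability
#'   additionally depends on `censoring_covariate` with log-odds
#'   `censoring_effect`
#' @param censoring_covariate,censoring_effect see above
#' @param effect_mode `"itt"`: the generative effect applies for
#'   `followup_days` from initiation regardless of stopping; `"pp"`: only
#'   while fills cover the calendar day
#' @param competing_death_rate,emigration_rate per 1000 person-years
#' @param package_sizes DDD per package choices (days of coverage at one
#'   DDD per day)
#' @param fixed_product_frac share of combined-oral initiators using a
#'   fixed combined product rather than self-combining two prescriptions
#' @param covariate_marginals category probabilities for the demographic
#'   covariates (defaults mirror published non-initiator margins)
#' @param frac_prior_mht,frac_prior_disease,frac_procedure,
#'   frac_late_registration fractions of women carrying each
#'   eligibility-violating history
#' @param fatal_event_frac share of recorded arterial events that are fatal
#'   on the event day (recorded via the cause-of-death register)
#' @param seed master seed; per-table streams are derived from it
#' @return a validated list of class `mht_scenario`
#' @export
simulation_scenario <- function(
    n_women = 10000L,
    study_start = as.Date("2007-07-01"),
    study_end = as.Date("2018-12-01"),
    followup_days = 730L,
    baseline_rates = c(ihd = 2.55, cerebral_infarction = 1.01, vte = 2.26),
    mi_fraction = 0.42,
    true_hr = list(),
    strategy_mix = default_strategy_mix(),
    monthly_init_prob = 0.0008,
    monthly_stop_prob = 0.051,
    confounding_strength = c(med_heart_disease = 0.25, med_hypertension = 0.13,
                             med_diabetes = -0.32, urban = 0.33,
                             elementary_education = -0.35),
    hazard_only_strength = numeric(),
    informative_censoring = FALSE,
    censoring_covariate = "urban",
    censoring_effect = 0,
    effect_mode = c("itt", "pp"),
    competing_death_rate = 2.0,
    emigration_rate = 1.5,
    package_sizes = c(28L, 42L, 84L),
    fixed_product_frac = 0.5,
    covariate_marginals = default_covariate_marginals(),
    frac_prior_mht = 0.05,
    frac_prior_disease = 0.03,
    frac_procedure = 0.04,
    frac_late_registration = 0.02,
    fatal_event_frac = 0.05,
    seed = 1L) {
  sc <- list(n_women = as.integer(n_women),
             study_start = as.Date(study_start),
             study_end = as.Date(study_end),
             followup_days = as.integer(followup_days),
             baseline_rates = baseline_rates, mi_fraction = mi_fraction,
             true_hr = true_hr, strategy_mix = strategy_mix,
             monthly_init_prob = monthly_init_prob,
             monthly_stop_prob = monthly_stop_prob,
             confounding_strength = confounding_strength,
             hazard_only_strength = hazard_only_strength,
             informative_censoring = isTRUE(informative_censoring),
             censoring_covariate = censoring_covariate,
             censoring_effect = censoring_effect,
             effect_mode = match.arg(effect_mode),
             competing_death_rate = competing_death_rate,
             emigration_rate = emigration_rate,
             package_sizes = as.integer(package_sizes),
             fixed_product_frac = fixed_product_frac,
             covariate_marginals = covariate_marginals,
             frac_prior_mht = frac_prior_mht,
             frac_prior_disease = frac_prior_disease,
             frac_procedure = frac_procedure,
             frac_late_registration = frac_late_registration,
             fatal_event_frac = fatal_event_frac,
             seed = as.integer(seed))
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  if (sc$n_women < 1L) stop("n_women must be positive", call. = FALSE)
  if (!is_month_aligned(c(sc$study_start, sc$study_end)) ||
      sc$study_start > sc$study_end)
    stop("study window must be month-aligned with start <= end", call. = FALSE)
  if (abs(sum(sc$strategy_mix) - 1) > 1e-6)
    stop("strategy_mix must sum to 1", call. = FALSE)
  if (!setequal(names(sc$strategy_mix), INITIATOR_STRATEGIES))
    stop("strategy_mix must be named by the 7 initiator strategies",
         call. = FALSE)
  if (any(sc$baseline_rates < 0) || sc$competing_death_rate < 0 ||
      sc$emigration_rate < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (!setequal(names(sc$baseline_rates), SIM_OUTCOME_CAUSES))
    stop("baseline_rates must be named ihd, cerebral_infarction, vte",
         call. = FALSE)
  if (sc$monthly_stop_prob < 0 || sc$monthly_stop_prob > 1 ||
      sc$monthly_init_prob < 0 || sc$monthly_init_prob > 1)
    stop("monthly probabilities must lie in [0, 1]", call. = FALSE)
  for (s in names(sc$true_hr)) {
    if (!(s %in% INITIATOR_STRATEGIES))
      stop("true_hr names unknown strategy: ", s, call. = FALSE)
    hr <- sc$true_hr[[s]]
    bad <- setdiff(names(hr),
                   c(SIM_OUTCOME_CAUSES, "composite_cvd", "mi", "death"))
    if (length(bad))
      stop("true_hr[[", s, "]] names unknown outcome(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(hr <= 0)) stop("true_hr must be positive", call. = FALSE)
  }
  structure(sc, class = "mht_scenario")
}

#' @export
print.mht_scenario <- function(x, ...) {
  cat("Synthetic registry scenario\n")
  cat(sprintf("  %d women, trials %s .. %s, follow-up %d days\n",
              x$n_women, format(x$study_start), format(x$study_end),
              x$followup_days))
  cat(sprintf("  baseline rates /1000py: ihd %.2f, cerebral %.2f, vte %.2f\n",
              x$baseline_rates["ihd"], x$baseline_rates["cerebral_infarction"],
              x$baseline_rates["vte"]))
  cat(sprintf("  monthly initiation %.4f, monthly stop %.3f, mode %s, seed %d\n",
              x$monthly_init_prob, x$monthly_stop_prob, x$effect_mode, x$seed))
  invisible(x)
}

## deterministic per-table seed stream from one master seed
stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629) + 1L
}

## linear predictor from named effect vector; supported covariate handles
confounder_lp <- function(strength, gt) {
  if (!length(strength)) return(numeric(nrow(gt)))
  lp <- numeric(nrow(gt))
  for (nm in names(strength)) {
    x <- switch(nm,
      med_hypertension = gt$med_hypertension,
      med_heart_disease = gt$med_heart_disease,
      med_diabetes = gt$med_diabetes,
      urban = gt$geo_region == "urban",
      rural = gt$geo_region == "rural",
      elementary_education = gt$education == "elementary",
      higher_education = gt$education %in% c("higher_education", "research"),
      non_nordic = gt$region_of_birth != "Nordics",
      age = (gt$age_at_start - 54) / 4,
      stop("unsupported confounder name: ", nm, call. = FALSE))
    lp <- lp + strength[[nm]] * as.numeric(x)
  }
  lp
}

#' Simulate the study population
#'
#' Draws demographics so the 50-58 age window is populated in every trial
#' month, covariates from the scenario's marginals, and the
#' eligibility-violating histories (late registration, prior surgical
#' procedures).  Death and emigration dates are filled in by
#' [simulate_outcomes()].  The latent per-woman state (covariate flags and
#' the initiation/outcome linear predictors) is attached as attribute
#' `ground_truth`; prior surgical procedure records as attribute
#' `procedures`.
#'
#' @param scenario an [simulation_scenario()]
#' @return persons data frame (persons schema) with attributes
#'   `ground_truth` and `procedures`
#' @export
simulate_population <- function(scenario) {
  sc <- validate_scenario(scenario)
  set.seed(stage_seed(sc$seed, 1L))
  n <- sc$n_women
  M <- year_month(sc$study_end) - year_month(sc$study_start) + 1L
  dur_years <- M / 12
  age_lo <- min(48, 50 - dur_years - 1)
  age0 <- stats::runif(n, age_lo, 60)
  birth <- sc$study_start - round(age0 * 365.25)
  cm <- sc$covariate_marginals
  draw <- function(m) sample(names(m), n, replace = TRUE, prob = m / sum(m))
  education <- draw(cm$education)
  region_of_birth <- draw(cm$region_of_birth)
  geo_region <- draw(cm$geo_region)
  med_hypertension <- stats::runif(n) < cm$med[["hypertension"]]
  med_heart_disease <- stats::runif(n) < cm$med[["heart_disease"]]
  med_diabetes <- stats::runif(n) < cm$med[["diabetes"]]
  late <- stats::runif(n) < sc$frac_late_registration
  first_registered <- as.Date(ifelse(late,
    as.Date("2006-06-01") + sample.int(2000L, n, replace = TRUE),
    as.Date("1990-01-01") + sample.int(5000L, n, replace = TRUE)),
    origin = "1970-01-01")
  person_id <- sprintf("W%07d", seq_len(n))
  persons <- data.frame(
    person_id = person_id, birth_date = birth, education = education,
    region_of_birth = region_of_birth, geo_region = geo_region,
    first_registered = first_registered,
    death_date = as.Date(NA), emigration_date = as.Date(NA),
    stringsAsFactors = FALSE)

  gt <- data.frame(person_id = person_id, age_at_start = age0,
                   education = education, region_of_birth = region_of_birth,
                   geo_region = geo_region,
                   med_hypertension = med_hypertension,
                   med_heart_disease = med_heart_disease,
                   med_diabetes = med_diabetes,
                   prior_disease = stats::runif(n) < sc$frac_prior_disease,
                   prior_mht = stats::runif(n) < sc$frac_prior_mht,
                   stringsAsFactors = FALSE)
  gt$lp_init <- confounder_lp(sc$confounding_strength, gt)
  gt$lp_out <- gt$lp_init + confounder_lp(sc$hazard_only_strength, gt)
  gt$x_cens <- if (sc$informative_censoring)
    as.numeric(confounder_lp(stats::setNames(1, sc$censoring_covariate), gt))
  else numeric(n)

  ## prior surgical histories; half of the unilateral-oophorectomy women get
  ## a second record on a distinct date (which disqualifies), half only one
  has_proc <- which(stats::runif(n) < sc$frac_procedure)
  procedures <- data.frame(person_id = character(), event_date = as.Date(character()),
                           procedure = character(), stringsAsFactors = FALSE)
  if (length(has_proc)) {
    type <- sample(PROCEDURE_LEVELS, length(has_proc), replace = TRUE)
    d1 <- sc$study_start - sample(200:4000, length(has_proc), replace = TRUE)
    procedures <- data.frame(person_id = person_id[has_proc], event_date = d1,
                             procedure = type, stringsAsFactors = FALSE)
    uni <- has_proc[type == "unilateral_oophorectomy"]
    second <- uni[seq_along(uni) %% 2L == 0L]
    if (length(second)) {
      j <- match(second, has_proc)
      procedures <- rbind(procedures, data.frame(
        person_id = person_id[second],
        event_date = d1[j] + sample(30:400, length(second), replace = TRUE),
        procedure = "unilateral_oophorectomy", stringsAsFactors = FALSE))
    }
  }
  attr(persons, "ground_truth") <- gt
  attr(persons, "procedures") <- procedures
  persons
}

## composition of fills per strategy; returns a data.frame template with one
## row per component per fill
strategy_fill_rows <- function(strategy, fixed) {
  comp <- switch(strategy,
    tibolone = data.frame(atc_code = "G03CX01", route = "oral",
                          hormone_content = "tibolone",
                          oestrogen_dose = 0, progestogen_dose = 0),
    oral_unopposed_oestrogen = data.frame(
      atc_code = "G03CA03", route = "oral",
      hormone_content = "oestrogen_only",
      oestrogen_dose = 2, progestogen_dose = 0),
    oral_oestrogen_lng_ius = data.frame(
      atc_code = "G03CA03", route = "oral",
      hormone_content = "oestrogen_only",
      oestrogen_dose = 2, progestogen_dose = 0),
    transdermal_unopposed_oestrogen = data.frame(
      atc_code = "G03CA03", route = "transdermal",
      hormone_content = "oestrogen_only",
      oestrogen_dose = 0.05, progestogen_dose = 0),
    transdermal_combined = data.frame(
      atc_code = c("G03CA03", "G03DC02"), route = c("transdermal", "oral"),
      hormone_content = c("oestrogen_only", "progestogen_only"),
      oestrogen_dose = c(0.05, 0), progestogen_dose = c(0, 10)),
    oral_combined_continuous = if (fixed) data.frame(
      atc_code = "G03FA01", route = "oral",
      hormone_content = "fixed_combined_continuous",
      oestrogen_dose = 2, progestogen_dose = 1)
    else data.frame(
      atc_code = c("G03CA03", "G03DC02"), route = "oral",
      hormone_content = c("oestrogen_only", "progestogen_only"),
      oestrogen_dose = c(2, 0), progestogen_dose = c(0, 0.5)),
    oral_combined_sequential = if (fixed) data.frame(
      atc_code = "G03FB05", route = "oral",
      hormone_content = "fixed_combined_sequential",
      oestrogen_dose = 2, progestogen_dose = 1)
    else data.frame(
      atc_code = c("G03CA03", "G03DC02"), route = "oral",
      hormone_content = c("oestrogen_only", "progestogen_only"),
      oestrogen_dose = c(2, 0), progestogen_dose = c(0, 0.2)),
    stop("unknown strategy: ", strategy, call. = FALSE))
  comp
}

#' Simulate dispensation records
#'
#' Initiation is drawn month by month on the logit scale (baseline
#' `monthly_init_prob` plus the confounding linear predictor) while a woman
#' is aged 50-58; each initiator receives a first fill in her initiation
#' month and then refills at package-coverage intervals until a geometric
#' stop whose per-cycle probability matches `monthly_stop_prob` per 30 days
#' (optionally shifted by the informative-censoring covariate).
#' Self-combined arms are emitted as paired oestrogen-only plus
#' progestogen-only dispensations with the dose ratio on the intended side
#' of 7; the LNG-IUS is a single insertion record.  Medication-covariate
#' fills (antihypertensives, heart medication, antidiabetics) are emitted
#' quarterly for flagged women so that covariate lookback windows find
#' them; prior-MHT women carry one fill shortly before the study start.
#'
#' @param population output of [simulate_population()]
#' @param scenario the same [simulation_scenario()]
#' @return dispensations data frame with updated attribute `ground_truth`
#'   (initiation date, strategy, treatment end)
#' @export
simulate_dispensations <- function(population, scenario) {
  sc <- validate_scenario(scenario)
  set.seed(stage_seed(sc$seed, 2L))
  gt <- attr(population, "ground_truth")
  stopifnot(!is.null(gt))
  n <- nrow(gt)
  M <- year_month(sc$study_end) - year_month(sc$study_start) + 1L

  ## initiation month: geometric over the months in the study window during
  ## which the woman is aged 50-58 (continuous-age approximation)
  m_lo <- pmax(1L, as.integer(ceiling((50 - gt$age_at_start) * 12)) + 1L)
  m_hi <- pmin(M, as.integer(floor((59 - gt$age_at_start) * 12)))
  p_init <- stats::plogis(stats::qlogis(sc$monthly_init_prob) + gt$lp_init)
  if (sc$monthly_init_prob == 0) p_init[] <- 0
  g <- ifelse(p_init > 0, stats::rgeom(n, pmin(p_init, 1 - 1e-12)), NA_integer_)
  m_init <- m_lo + g
  initiates <- !is.na(m_init) & m_init <= m_hi & m_lo <= m_hi
  strategy <- rep("non_initiator", n)
  ninit <- sum(initiates)
  rows <- list()
  init_date <- rep(as.Date(NA), n)
  treat_end <- rep(as.Date(NA), n)
  n_fills <- integer(n)
  if (ninit > 0L) {
    strategy[initiates] <- sample(names(sc$strategy_mix), ninit,
                                  replace = TRUE, prob = sc$strategy_mix)
    idx <- which(initiates)
    first <- add_months(sc$study_start, m_init[idx] - 1L) +
      sample.int(28L, ninit, replace = TRUE) - 1L
    pkg <- if (length(sc$package_sizes) == 1L)
      rep(sc$package_sizes, ninit)
    else sample(sc$package_sizes, ninit, replace = TRUE)
    p_stop <- if (sc$informative_censoring)
      stats::plogis(stats::qlogis(pmin(pmax(sc$monthly_stop_prob, 1e-12),
                                       1 - 1e-12)) +
                      sc$censoring_effect * gt$x_cens[idx])
    else rep(sc$monthly_stop_prob, ninit)
    q <- (1 - p_stop)^(pkg / 30)          # per-cycle continuation
    k_max <- pmax(1L, as.integer(ceiling((sc$followup_days + 90) / pkg)) + 1L)
    nf <- ifelse(q >= 1, k_max,
                 pmin(1L + stats::rgeom(ninit, pmax(1 - q, 1e-12)), k_max))
    init_date[idx] <- first
    treat_end[idx] <- first + nf * pkg
    n_fills[idx] <- nf
    fixed <- stats::runif(ninit) < sc$fixed_product_frac

    ## expand: per initiator, nf fills x component rows
    for (s in INITIATOR_STRATEGIES) {
      for (fx in unique(fixed)) {
        sel <- which(strategy[idx] == s & fixed == fx)
        if (!length(sel)) next
        comp <- strategy_fill_rows(s, fx)
        nc <- nrow(comp)
        reps <- nf[sel]
        pid <- rep(gt$person_id[idx][sel], reps * nc)
        fill_no <- unlist(lapply(reps, function(k) rep(seq_len(k) - 1L,
                                                       each = nc)))
        pkg_i <- rep(pkg[sel], reps * nc)
        dates <- rep(first[sel], reps * nc) + fill_no * pkg_i
        ci <- unlist(lapply(reps, function(k) rep.int(seq_len(nc), k)))
        rows[[length(rows) + 1L]] <- data.frame(
          person_id = pid, dispense_date = dates,
          atc_code = comp$atc_code[ci], route = comp$route[ci],
          hormone_content = comp$hormone_content[ci],
          oestrogen_dose = comp$oestrogen_dose[ci],
          progestogen_dose = comp$progestogen_dose[ci],
          n_packages = 1L, ddd_per_package = pkg_i,
          stringsAsFactors = FALSE)
      }
    }
    ## LNG-IUS insertion record at initiation for that arm
    lng <- which(strategy[idx] == "oral_oestrogen_lng_ius")
    if (length(lng))
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = gt$person_id[idx][lng], dispense_date = first[lng],
        atc_code = "G02BA03", route = "local", hormone_content = "lng_ius",
        oestrogen_dose = 0, progestogen_dose = 0.02,
        n_packages = 1L, ddd_per_package = 1L, stringsAsFactors = FALSE)
  }

  ## prior MHT use shortly before study start (washout violations early on)
  prior <- which(gt$prior_mht)
  if (length(prior))
    rows[[length(rows) + 1L]] <- data.frame(
      person_id = gt$person_id[prior],
      dispense_date = sc$study_start - sample(30:600, length(prior),
                                              replace = TRUE),
      atc_code = "G03CA03", route = "oral", hormone_content = "oestrogen_only",
      oestrogen_dose = 2, progestogen_dose = 0,
      n_packages = 1L, ddd_per_package = 28L, stringsAsFactors = FALSE)

  ## quarterly medication-covariate fills for flagged women
  med_specs <- list(
    c(flag = "med_hypertension", atc = "C03AA03"),
    c(flag = "med_heart_disease", atc = "C07AB02"),
    c(flag = "med_diabetes", atc = "A10BA02"))
  med_dates <- seq(sc$study_start - 365L, sc$study_end + 60L, by = 91L)
  for (spec in med_specs) {
    who <- which(gt[[spec[["flag"]]]])
    if (!length(who)) next
    rows[[length(rows) + 1L]] <- data.frame(
      person_id = rep(gt$person_id[who], each = length(med_dates)),
      dispense_date = rep(med_dates, length(who)),
      atc_code = spec[["atc"]], route = "oral", hormone_content = "none",
      oestrogen_dose = 0, progestogen_dose = 0,
      n_packages = 1L, ddd_per_package = 100L, stringsAsFactors = FALSE)
  }

  disp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(person_id = character(), dispense_date = as.Date(character()),
               atc_code = character(), route = character(),
               hormone_content = character(), oestrogen_dose = numeric(),
               progestogen_dose = numeric(), n_packages = integer(),
               ddd_per_package = integer(), stringsAsFactors = FALSE)
  disp <- disp[order(disp$person_id, disp$dispense_date), , drop = FALSE]
  rownames(disp) <- NULL
  gt$strategy <- strategy
  gt$init_date <- init_date
  gt$treatment_end <- treat_end
  gt$n_mht_fills <- n_fills
  attr(disp, "ground_truth") <- gt
  disp
}

hr_lookup <- function(true_hr, strategy, cause) {
  out <- rep(1, length(strategy))
  for (s in names(true_hr)) {
    hr <- true_hr[[s]]
    v <- if (cause %in% names(hr)) hr[[cause]]
    else if (cause %in% c("ihd", "cerebral_infarction") &&
             "composite_cvd" %in% names(hr)) hr[["composite_cvd"]]
    else 1
    out[strategy == s] <- v
  }
  out
}

## piecewise-exponential first-event time: daily hazard h before exposure
## and after it, h*hr inside [a, b); offsets in days from entry, horizon T
piecewise_exp_time <- function(n, T, a, b, h, hr) {
  E <- stats::rexp(n)
  a <- pmin(pmax(a, 0), T)
  b <- pmin(pmax(b, a), T)
  H1 <- h * a
  H2 <- H1 + h * hr * (b - a)
  t <- ifelse(E < H1, E / h,
              ifelse(E < H2, a + (E - H1) / (h * hr),
                     b + (E - H2) / h))
  ifelse(t <= T, t, Inf)
}

#' Simulate outcome, death and emigration records
#'
#' Cause-specific first-event times are drawn from exponential hazards
#' (baseline rate x exp(outcome linear predictor)), multiplied by the
#' strategy's true hazard ratio while the woman is generatively exposed
#' (from initiation for the full follow-up under `effect_mode = "itt"`, or
#' only while fills cover the day under `"pp"`).  The first event per cause
#' is recorded with a matching ICD-10 code (ihd events are coded I21/I22
#' with probability `mi_fraction`, else I20/I24/I25).  Death and emigration
#' are competing exponential processes; records after death or emigration
#' are not emitted; a fraction of arterial events is fatal on the event
#' day and sourced from the cause-of-death register.  Prior-disease
#' women receive an exclusion diagnosis before the study start.
#'
#' @param population output of [simulate_population()]
#' @param dispensations output of [simulate_dispensations()]
#' @param scenario the same [simulation_scenario()]
#' @return diagnoses data frame; attribute `persons` carries the persons
#'   table with death/emigration dates filled in, attribute `ground_truth`
#'   the final latent state (exposure window, latent event days)
#' @export
simulate_outcomes <- function(population, dispensations, scenario) {
  sc <- validate_scenario(scenario)
  set.seed(stage_seed(sc$seed, 3L))
  gt <- attr(dispensations, "ground_truth") %||% attr(population, "ground_truth")
  stopifnot(!is.null(gt), !is.null(gt$strategy))
  n <- nrow(gt)
  entry <- as.integer(sc$study_start)
  horizon <- as.integer(sc$study_end) + sc$followup_days
  T <- horizon - entry
  es <- ifelse(is.na(gt$init_date), Inf, as.integer(gt$init_date) - entry)
  ee <- if (sc$effect_mode == "itt") es + sc$followup_days
  else ifelse(is.na(gt$treatment_end), Inf,
              as.integer(gt$treatment_end) - entry)
  ee <- pmin(ee, ifelse(is.finite(es), Inf, -Inf))
  ee[!is.finite(es)] <- -Inf
  es[!is.finite(es)] <- -1

  base_daily <- function(rate) rate / 1000 / 365.25
  lam <- exp(gt$lp_out)
  t_cause <- list()
  for (cause in SIM_OUTCOME_CAUSES) {
    h <- base_daily(sc$baseline_rates[[cause]]) * lam
    hr <- hr_lookup(sc$true_hr, gt$strategy, cause)
    t_cause[[cause]] <- piecewise_exp_time(n, T, es, ee, h, hr)
  }
  h_death <- base_daily(sc$competing_death_rate) * lam
  hr_death <- hr_lookup(sc$true_hr, gt$strategy, "death")
  t_death <- piecewise_exp_time(n, T, es, ee, h_death, hr_death)
  t_emig <- ifelse(sc$emigration_rate > 0,
                   stats::rexp(n, base_daily(sc$emigration_rate)), Inf)
  t_emig <- ifelse(t_emig <= T, t_emig, Inf)

  t_out <- pmin(t_death, t_emig)
  mk_date <- function(t) as.Date(entry + ceiling(t), origin = "1970-01-01")

  dx <- list()
  for (cause in SIM_OUTCOME_CAUSES) {
    t <- t_cause[[cause]]
    rec <- is.finite(t) & t <= t_out
    if (!any(rec)) next
    nrec <- sum(rec)
    code <- switch(cause,
      ihd = ifelse(stats::runif(nrec) < sc$mi_fraction,
                   sample(c("I21", "I22"), nrec, replace = TRUE),
                   sample(c("I20", "I24", "I25"), nrec, replace = TRUE)),
      cerebral_infarction = rep("I63", nrec),
      vte = sample(c("I26", "I80", "I81", "I82"), nrec, replace = TRUE))
    dx[[cause]] <- data.frame(
      person_id = gt$person_id[rec], event_date = mk_date(t[rec]),
      icd10_code = code, source = "patient_register",
      cause = cause, stringsAsFactors = FALSE)
  }
  diagnoses <- if (length(dx)) do.call(rbind, dx) else
    data.frame(person_id = character(), event_date = as.Date(character()),
               icd10_code = character(), source = character(),
               cause = character(), stringsAsFactors = FALSE)

  ## fatal arterial events: recorded via the cause-of-death register and
  ## terminating follow-up on the event day
  death_day <- ifelse(is.finite(t_death), ceiling(t_death), NA_real_)
  if (nrow(diagnoses) && sc$fatal_event_frac > 0) {
    art <- which(diagnoses$cause %in% c("ihd", "cerebral_infarction"))
    fatal <- art[stats::runif(length(art)) < sc$fatal_event_frac]
    if (length(fatal)) {
      diagnoses$source[fatal] <- "cause_of_death"
      j <- match(diagnoses$person_id[fatal], gt$person_id)
      ev_day <- as.integer(diagnoses$event_date[fatal]) - entry
      death_day[j] <- pmin(death_day[j], ev_day, na.rm = TRUE)
    }
  }
  emig_day <- ifelse(is.finite(t_emig), ceiling(t_emig), NA_real_)
  ## emigration cannot follow death and vice versa: keep the earlier
  emig_day[!is.na(death_day) & !is.na(emig_day) &
             death_day <= emig_day] <- NA
  death_day[!is.na(death_day) & !is.na(emig_day) &
              emig_day < death_day] <- NA

  persons <- population
  j <- match(gt$person_id, persons$person_id)
  persons$death_date[j] <- as.Date(entry + death_day, origin = "1970-01-01")
  persons$emigration_date[j] <- as.Date(entry + emig_day,
                                        origin = "1970-01-01")

  ## drop records after the terminal date
  term <- as.integer(pmin(persons$death_date[match(diagnoses$person_id,
                                                   persons$person_id)],
                          persons$emigration_date[match(diagnoses$person_id,
                                                        persons$person_id)],
                          na.rm = TRUE))
  keep <- is.na(term) | as.integer(diagnoses$event_date) <= term
  diagnoses <- diagnoses[keep, , drop = FALSE]

  ## prior-disease exclusion diagnoses before the study start
  prior <- which(gt$prior_disease)
  if (length(prior))
    diagnoses <- rbind(diagnoses, data.frame(
      person_id = gt$person_id[prior],
      event_date = sc$study_start - sample(30:3650, length(prior),
                                           replace = TRUE),
      icd10_code = sample(c("I259", "C509"), length(prior), replace = TRUE),
      source = "patient_register", cause = "prior_disease",
      stringsAsFactors = FALSE))

  diagnoses <- diagnoses[order(diagnoses$person_id, diagnoses$event_date), ]
  rownames(diagnoses) <- NULL
  gt$exposure_start <- ifelse(es < 0, NA_real_, es)
  gt$exposure_end <- ifelse(ee < 0, NA_real_, ee)
  for (cause in SIM_OUTCOME_CAUSES)
    gt[[paste0("t_", cause)]] <- ifelse(is.finite(t_cause[[cause]]),
                                        t_cause[[cause]], NA_real_)
  gt$t_death <- ifelse(is.finite(t_death), t_death, NA_real_)
  out <- diagnoses[c("person_id", "event_date", "icd10_code", "source")]
  attr(out, "persons") <- persons
  attr(out, "ground_truth") <- gt
  out
}

#' Generate a complete synthetic registry bundle
#'
#' Runs [simulate_population()], [simulate_dispensations()] and
#' [simulate_outcomes()] on per-table random streams derived from the
#' scenario's master seed, and assembles the validated registry.
#'
#' @param scenario an [simulation_scenario()]
#' @return an `mht_registry` with attributes `ground_truth` (one row per
#'   woman: latent covariate state, initiation date, strategy, exposure
#'   window, latent event days) and `scenario`
#' @export
simulate_registry <- function(scenario) {
  sc <- validate_scenario(scenario)
  population <- simulate_population(sc)
  dispensations <- simulate_dispensations(population, sc)
  diagnoses <- simulate_outcomes(population, dispensations, sc)
  persons <- attr(diagnoses, "persons")
  gt <- attr(diagnoses, "ground_truth")
  reg <- new_registry(persons, dispensations,
                      diagnoses,
                      attr(population, "procedures"))
  attr(reg, "ground_truth") <- gt
  attr(reg, "scenario") <- sc
  reg
}

#' Hazard ratio giving a target one-year risk difference
#'
#' For an exponential cause-specific hazard with annual rate
#' `rate_per_1000 / 1000`, returns the hazard ratio `h` such that the
#' one-year cumulative incidence under `h` exceeds the baseline one-year
#' cumulative incidence by exactly `risk_difference` (competing risks
#' ignored, appropriate when they are rare over one year).  Used to
#' calibrate effect-recovery scenarios by closed form.
#'
#' @param rate_per_1000 baseline events per 1000 person-years
#' @param risk_difference target absolute one-year risk difference
#' @return the hazard ratio
#' @export
hr_for_risk_difference <- function(rate_per_1000, risk_difference) {
  lam <- rate_per_1000 / 1000
  p0 <- 1 - exp(-lam)
  p1 <- p0 + risk_difference
  if (p1 >= 1 || p1 <= 0) stop("unattainable risk difference", call. = FALSE)
  log(1 - p1) / log(1 - p0)
}
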