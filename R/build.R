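## Stack eligible person-trials, ascertain outcomes under the
## cause-specific censoring conventions, and emit the analysis-ready
## dataset.

OUTCOMES <- c("composite_cvd", "ihd", "mi", "cerebral_infarction", "vte")
FOLLOWUP_STATUSES <- c("event", "competing_event", "death", "emigrated",
                       "admin_censored", "pp_censored")

## Atomic diagnosis categories: myocardial infarction (I21/I22), other
## ischaemic heart disease, cerebral infarction, venous thromboembolism.
## MI is a subset of IHD, so MI events never compete against the IHD or MI
## analyses; whether VTE competes against the arterial outcomes (and vice
## versa) is a configuration switch, on by default.
atomic_code_sets <- function(codebook) {
  oc <- codebook$outcome_codes
  list(mi = oc$mi,
       ihd_other = setdiff(oc$ihd, oc$mi),
       cerebral = oc$cerebral_infarction,
       vte = oc$vte)
}

outcome_event_sets <- function(outcome, vte_competes = TRUE) {
  ev <- switch(outcome,
    composite_cvd = c("mi", "ihd_other", "cerebral"),
    ihd = c("mi", "ihd_other"),
    mi = "mi",
    cerebral_infarction = "cerebral",
    vte = "vte",
    stop("unknown outcome: ", outcome, call. = FALSE))
  comp <- switch(outcome,
    composite_cvd = if (vte_competes) "vte" else character(),
    ihd = c("cerebral", if (vte_competes) "vte"),
    mi = c("ihd_other", "cerebral", if (vte_competes) "vte"),
    cerebral_infarction = c("mi", "ihd_other", if (vte_competes) "vte"),
    vte = if (vte_competes) c("mi", "ihd_other", "cerebral") else character())
  list(event = ev, competing = comp)
}

## first matching diagnosis day (relative to s, in (0, fu]) per person
first_cat_day <- function(cat_tab, pid, s, fu) {
  out <- rep(NA_integer_, length(pid))
  if (is.null(cat_tab) || nrow(cat_tab) == 0L) return(out)
  sub <- cat_tab[cat_tab$day > s & cat_tab$day <= s + fu, , drop = FALSE]
  if (!nrow(sub)) return(out)
  m <- tapply(sub$day, sub$person_id, min)
  j <- match(pid, names(m))
  hit <- !is.na(j)
  out[hit] <- as.integer(m[j[hit]]) - s
  out
}

resolve_outcome <- function(ev, comp, death, emig, fu) {
  ## earliest terminal state; ties resolved event > competing > death >
  ## emigrated > administrative censoring
  n <- length(ev)
  cand <- cbind(ev, comp, death, emig, rep(fu, n))
  time <- pmin(ev, comp, death, emig, rep(fu, n), na.rm = TRUE)
  pick <- function(col) !is.na(cand[, col]) & cand[, col] == time
  status <- rep("admin_censored", n)
  status[pick(4L)] <- "emigrated"
  status[pick(3L)] <- "death"
  status[pick(2L)] <- "competing_event"
  status[pick(1L)] <- "event"
  list(time = as.integer(time), status = status)
}

#' Build the stacked person-trial analysis dataset
#'
#' One row per eligible (woman, trial) with the assigned strategy, baseline
#' covariates frozen at the trial start (age in years, trial month 1..K,
#' calendar year, education, geographical region, region of birth, and
#' medication flags from an ATC lookback window before baseline) and, per
#' outcome, the follow-up time in days and terminal status.  Follow-up runs
#' to the first of: outcome event, competing event, death, emigration, or
#' administrative end of follow-up.
#'
#' @param eligibility decisions from [screen_trials()]
#' @param assignments strategies from [assign_strategies()]
#' @param registry an `mht_registry`
#' @param codebook an `mht_codebook`
#' @param trials an `mht_trials` data frame
#' @param outcomes outcomes to ascertain (default all five)
#' @param med_lookback_days window before baseline for the medication
#'   covariates (default 365)
#' @param vte_competes should venous thromboembolism censor the arterial
#'   analyses and vice versa (default `TRUE`)
#' @return a data frame, one row per person-trial, with covariates and
#'   `time_<outcome>` / `status_<outcome>` columns
#' @export
build_person_trials <- function(eligibility, assignments, registry, codebook,
                                trials, outcomes = OUTCOMES,
                                med_lookback_days = 365L,
                                vte_competes = TRUE) {
  elig <- eligibility[eligibility$eligible, , drop = FALSE]
  akey <- paste(assignments$person_id, assignments$trial_index)
  p <- registry$persons
  d <- registry$dispensations
  cats <- atomic_code_sets(codebook)
  dx <- registry$diagnoses
  cat_tabs <- lapply(cats, function(codes) {
    sub <- dx[code_match(dx$icd10_code, codes), , drop = FALSE]
    data.frame(person_id = sub$person_id,
               day = as.integer(sub$event_date))
  })
  med_tabs <- lapply(codebook$covariate_atc, function(codes) {
    sub <- d[code_match(d$atc_code, codes), , drop = FALSE]
    data.frame(person_id = sub$person_id,
               day = as.integer(sub$dispense_date))
  })
  birth <- as.integer(p$birth_date)
  death <- as.integer(p$death_date)
  emig <- as.integer(p$emigration_date)

  out <- vector("list", nrow(trials))
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    rows <- elig[elig$trial_index == tr$trial_index, , drop = FALSE]
    if (!nrow(rows)) next
    pid <- rows$person_id
    ai <- match(paste(pid, tr$trial_index), akey)
    if (anyNA(ai))
      stop(sprintf("missing strategy assignment for %d eligible women in trial %d",
                   sum(is.na(ai)), tr$trial_index), call. = FALSE)
    s <- as.integer(as.Date(tr$start_date))
    fu <- tr$followup_days
    j <- match(pid, p$person_id)
    df <- data.frame(
      person_id = pid,
      trial_index = tr$trial_index,
      trial_start = as.Date(s, origin = "1970-01-01"),
      strategy = assignments$strategy[ai],
      stringsAsFactors = FALSE)
    df$initiator <- df$strategy != "non_initiator"
    df$age <- (s - birth[j]) / 365.25
    df$trial_month <- tr$trial_index
    df$calendar_year <- as.POSIXlt(as.Date(s, origin = "1970-01-01"))$year + 1900L
    df$education <- p$education[j]
    df$geo_region <- p$geo_region[j]
    df$region_of_birth <- p$region_of_birth[j]
    for (nm in names(med_tabs)) {
      tab <- med_tabs[[nm]]
      sub <- tab[tab$day >= s - med_lookback_days & tab$day < s, "person_id"]
      df[[paste0("med_", nm)]] <- pid %in% sub
    }
    cat_days <- lapply(cat_tabs, first_cat_day, pid = pid, s = s, fu = fu)
    ## an eligible woman cannot have a pre-baseline arterial event (they
    ## are exclusion diagnoses); treat one as an upstream inconsistency
    for (cat in c("mi", "ihd_other", "cerebral")) {
      tab <- cat_tabs[[cat]]
      pre <- tab$person_id[tab$day < s]
      if (any(pid %in% pre))
        stop("diagnosis before trial start for an eligible woman ",
             "(eligibility screen and diagnosis table disagree)",
             call. = FALSE)
    }
    d_death <- ifelse(!is.na(death[j]) & death[j] - s <= fu & death[j] > s,
                      death[j] - s, NA_integer_)
    d_emig <- ifelse(!is.na(emig[j]) & emig[j] - s <= fu & emig[j] > s,
                     emig[j] - s, NA_integer_)
    for (oo in outcomes) {
      sets <- outcome_event_sets(oo, vte_competes)
      ev <- do.call(pmin, c(cat_days[sets$event], list(na.rm = TRUE)))
      comp <- if (length(sets$competing))
        do.call(pmin, c(cat_days[sets$competing], list(na.rm = TRUE)))
      else rep(NA_integer_, length(pid))
      r <- resolve_outcome(ev, comp, d_death, d_emig, fu)
      df[[paste0("time_", oo)]] <- r$time
      df[[paste0("status_", oo)]] <- r$status
    }
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no eligible person-trials", call. = FALSE)
  rownames(res) <- NULL
  attr(res, "outcomes") <- outcomes
  attr(res, "vte_competes") <- vte_competes
  res
}

#' Ascertain one outcome for a single person-trial
#'
#' Single-row counterpart of the ascertainment performed by
#' [build_person_trials()], useful for spot checks: returns the follow-up
#' time (days, in (0, `followup_days`]) and terminal status for one woman
#' and trial baseline.
#'
#' @param person_id,trial_start identify the person-trial
#' @param diagnoses the diagnoses table
#' @param codebook an `mht_codebook`
#' @param outcome one of `r paste(OUTCOMES, collapse=", ")`
#' @param death_date,emigration_date optional terminal dates
#' @param followup_days administrative follow-up
#' @param vte_competes see [build_person_trials()]
#' @return a one-row data frame `time`, `status`
#' @export
ascertain_outcome <- function(person_id, trial_start, diagnoses, codebook,
                              outcome, death_date = as.Date(NA),
                              emigration_date = as.Date(NA),
                              followup_days = 730L, vte_competes = TRUE) {
  s <- as.integer(as.Date(trial_start))
  fu <- as.integer(followup_days)
  dxp <- diagnoses[diagnoses$person_id == person_id, , drop = FALSE]
  cats <- atomic_code_sets(codebook)
  cat_days <- lapply(cats, function(codes) {
    hit <- code_match(dxp$icd10_code, codes)
    days <- as.integer(dxp$event_date[hit]) - s
    days <- days[days > 0L & days <= fu]
    if (length(days)) min(days) else NA_integer_
  })
  sets <- outcome_event_sets(outcome, vte_competes)
  ev <- suppressWarnings(min(unlist(cat_days[sets$event]), na.rm = TRUE))
  comp <- suppressWarnings(min(unlist(cat_days[sets$competing]), na.rm = TRUE))
  ev <- if (is.finite(ev)) ev else NA_integer_
  comp <- if (is.finite(comp)) comp else NA_integer_
  dd <- as.integer(as.Date(death_date)) - s
  de <- as.integer(as.Date(emigration_date)) - s
  dd <- if (!is.na(dd) && dd > 0L && dd <= fu) dd else NA_integer_
  de <- if (!is.na(de) && de > 0L && de <= fu) de else NA_integer_
  r <- resolve_outcome(ev, comp, dd, de, fu)
  data.frame(time = r$time, status = r$status)
}

#' Descriptive incidence trends among women aged 50-58
#'
#' Person-years by calendar year among women aged 50-58 (completed years),
#' and first-ever events per cause divided by those person-years, scaled to
#' events per 10 000 women-years.
#'
#' @param diagnoses,persons registry tables
#' @param codebook an `mht_codebook`
#' @param years integer vector of calendar years
#' @param outcomes outcome ids (default all five)
#' @return a data frame with `year`, `person_years` and one rate column per
#'   outcome
#' @export
compute_incidence_trends <- function(diagnoses, persons, codebook,
                                     years, outcomes = OUTCOMES) {
  cats <- atomic_code_sets(codebook)
  ## first-ever day per person per outcome
  first_days <- lapply(outcomes, function(oo) {
    codes <- codebook$outcome_codes[[switch(oo, composite_cvd = "composite_cvd",
                                            ihd = "ihd", mi = "mi",
                                            cerebral_infarction = "cerebral_infarction",
                                            vte = "vte")]]
    sub <- diagnoses[code_match(diagnoses$icd10_code, codes), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    m <- tapply(as.integer(sub$event_date), sub$person_id, min)
    data.frame(person_id = names(m), day = as.integer(m))
  })
  names(first_days) <- outcomes
  birth <- as.POSIXlt(persons$birth_date)
  bday <- function(k) {
    b <- birth
    b$year <- b$year + k
    out <- as.integer(as.Date(b))
    ## a Feb 29 birthday may not exist k years on; use Mar 1
    bad <- is.na(out) & !is.na(birth$year)
    if (any(bad)) {
      b2 <- birth
      b2$year <- b2$year + k
      b2$mon[bad] <- 2L
      b2$mday[bad] <- 1L
      out[bad] <- as.integer(as.Date(b2))[bad]
    }
    out
  }
  a50 <- bday(50L)   # enters the age window
  a59 <- bday(59L)   # leaves it (day of 59th birthday)
  death <- as.integer(persons$death_date)
  emig <- as.integer(persons$emigration_date)
  stop_day <- pmin(a59, death, emig, na.rm = TRUE)
  out <- data.frame(year = years, person_years = NA_real_)
  for (oo in outcomes) out[[paste0("rate_", oo)]] <- NA_real_
  for (i in seq_along(years)) {
    y0 <- as.integer(as.Date(sprintf("%d-01-01", years[i])))
    y1 <- as.integer(as.Date(sprintf("%d-12-31", years[i])))
    overlap <- pmax(0, pmin(stop_day, y1 + 1L) - pmax(a50, y0))
    py <- sum(overlap) / 365.25
    out$person_years[i] <- py
    for (oo in outcomes) {
      fd <- first_days[[oo]]
      nev <- 0L
      if (!is.null(fd)) {
        j <- match(fd$person_id, persons$person_id)
        in_year <- fd$day >= y0 & fd$day <= y1
        in_age <- fd$day >= a50[j] & fd$day < a59[j]
        nev <- sum(in_year & in_age, na.rm = TRUE)
      }
      out[[paste0("rate_", oo)]][i] <- if (py > 0) nev / py * 1e4 else 0
    }
  }
  out
}
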