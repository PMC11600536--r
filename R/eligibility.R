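## Monthly nested-trial construction and the target-trial eligibility screen.

#' Build the sequence of monthly nested trials
#'
#' One emulated trial starts on the first day of every calendar month from
#' `study_start` through `study_end` inclusive.  The default study window,
#' July 2007 through December 2018, gives 138 trials.
#'
#' @param study_start,study_end month-aligned `Date`s (first of month)
#' @param washout_days length of the pre-baseline window with no MHT
#'   dispensation; 730 by default, 2190 for the six-year sensitivity screen
#' @param followup_days administrative follow-up per trial (default 730)
#' @param age_min,age_max eligible age window in completed years
#' @return a data frame of class `mht_trials` with one row per trial:
#'   `trial_index`, `start_date`, `washout_days`, `followup_days`,
#'   `age_min`, `age_max`
#' @examples
#' nrow(make_trial_sequence(as.Date("2007-07-01"), as.Date("2018-12-01")))
#' @export
make_trial_sequence <- function(study_start = as.Date("2007-07-01"),
                                study_end = as.Date("2018-12-01"),
                                washout_days = 730L,
                                followup_days = 730L,
                                age_min = 50L, age_max = 58L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (!is_month_aligned(c(study_start, study_end)))
    stop("study_start and study_end must be first-of-month dates",
         call. = FALSE)
  if (study_start > study_end)
    stop("study_start must not be after study_end", call. = FALSE)
  n <- year_month(study_end) - year_month(study_start) + 1L
  out <- data.frame(
    trial_index = seq_len(n),
    start_date = add_months(study_start, seq_len(n) - 1L),
    washout_days = as.integer(washout_days),
    followup_days = as.integer(followup_days),
    age_min = as.integer(age_min),
    age_max = as.integer(age_max)
  )
  class(out) <- c("mht_trials", "data.frame")
  out
}

ELIGIBILITY_CRITERIA <- c("age", "washout", "prior_disease", "procedure",
                          "dead", "emigrated", "late_registration")

## Pre-computed per-person lookups reused across trials.
eligibility_index <- function(registry, codebook) {
  p <- registry$persons
  d <- registry$dispensations
  dx <- registry$diagnoses
  pr <- registry$procedures
  id <- p$person_id

  mht <- d[code_match(d$atc_code, codebook$mht_atc), c("person_id", "dispense_date")]
  mht <- mht[order(match(mht$person_id, id), mht$dispense_date), ]

  excl <- dx[code_match(dx$icd10_code, codebook$exclusion_diagnosis_codes), ]
  first_excl <- rep(as.Date(NA), length(id))
  if (nrow(excl)) {
    agg <- tapply(as.integer(excl$event_date), excl$person_id, min)
    j <- match(names(agg), id)
    first_excl[j[!is.na(j)]] <- as.Date(as.integer(agg[!is.na(j)]),
                                        origin = "1970-01-01")
  }

  ## earliest date at which the surgical exclusion is satisfied: any
  ## hysterectomy / bilateral oophorectomy / sterilisation, or unilateral
  ## oophorectomy on a second distinct date
  proc_qual <- rep(as.Date(NA), length(id))
  if (nrow(pr)) {
    single <- pr[pr$procedure %in% c("hysterectomy", "bilateral_oophorectomy",
                                     "sterilisation"), ]
    if (nrow(single)) {
      agg <- tapply(as.integer(single$event_date), single$person_id, min)
      j <- match(names(agg), id)
      proc_qual[j] <- as.Date(as.integer(agg), origin = "1970-01-01")
    }
    uni <- pr[pr$procedure == "unilateral_oophorectomy", ]
    if (nrow(uni)) {
      second <- tapply(as.integer(uni$event_date), uni$person_id, function(v) {
        v <- sort(unique(v))
        if (length(v) >= 2L) v[2L] else NA_integer_
      })
      second <- second[!is.na(second)]
      if (length(second)) {
        j <- match(names(second), id)
        cur <- as.integer(proc_qual[j])
        proc_qual[j] <- as.Date(pmin(cur, as.integer(second), na.rm = TRUE),
                                origin = "1970-01-01")
      }
    }
  }

  list(persons = p, mht_fills = mht, first_exclusion = first_excl,
       procedure_qualified = proc_qual)
}

person_has_record_in_window <- function(records, ids, lo, hi) {
  ## records: data.frame(person_id, <date in col 2>); window [lo, hi)
  sub <- records[records[[2]] >= lo & records[[2]] < hi, 1L]
  ids %in% sub
}

#' Screen the study population for one trial month
#'
#' A woman is eligible at the trial start if and only if all of the
#' following hold: her age in completed years lies in the trial's age
#' window; she has no systemic MHT dispensation in the `washout_days`
#' half-open window ending the day before the trial start (a fill on the
#' boundary day counts as inside the washout); she has no exclusion
#' diagnosis, ever; she has no exclusion procedure (bilateral oophorectomy,
#' unilateral oophorectomy on two distinct dates, hysterectomy, or
#' sterilisation), ever; she is alive and not emigrated at the trial start;
#' and she first appears in the registers no later than the registration
#' cut-off (end of 2005).  `failed_criteria` lists every violated
#' criterion, not only the first.
#'
#' @param registry an `mht_registry`
#' @param codebook an `mht_codebook`
#' @param trial one row of [make_trial_sequence()]
#' @param registration_cutoff latest allowed first-registration date
#' @param index optional pre-computed [eligibility_index()]; supply it when
#'   screening many trials against the same registry
#' @return a data frame with one row per woman: `person_id`, `trial_index`,
#'   `eligible`, `failed_criteria` (comma-separated criterion ids, `""` when
#'   eligible)
#' @export
screen_trial <- function(registry, codebook, trial,
                         registration_cutoff = as.Date("2005-12-31"),
                         index = NULL) {
  if (is.null(index)) index <- eligibility_index(registry, codebook)
  p <- index$persons
  s <- as.Date(trial$start_date)
  age <- completed_years(p$birth_date, s)
  fail <- matrix(FALSE, nrow(p), length(ELIGIBILITY_CRITERIA),
                 dimnames = list(NULL, ELIGIBILITY_CRITERIA))
  fail[, "age"] <- age < trial$age_min | age > trial$age_max
  fail[, "washout"] <- person_has_record_in_window(
    index$mht_fills, p$person_id, s - trial$washout_days, s)
  fail[, "prior_disease"] <- !is.na(index$first_exclusion) &
    index$first_exclusion < s
  fail[, "procedure"] <- !is.na(index$procedure_qualified) &
    index$procedure_qualified < s
  fail[, "dead"] <- !is.na(p$death_date) & p$death_date <= s
  fail[, "emigrated"] <- !is.na(p$emigration_date) & p$emigration_date <= s
  fail[, "late_registration"] <- is.na(p$first_registered) |
    p$first_registered > registration_cutoff
  nfail <- rowSums(fail)
  failed <- character(nrow(p))
  has <- nfail > 0L
  if (any(has))
    failed[has] <- apply(fail[has, , drop = FALSE], 1L, function(r)
      paste(ELIGIBILITY_CRITERIA[r], collapse = ","))
  data.frame(person_id = p$person_id,
             trial_index = trial$trial_index,
             eligible = !has,
             failed_criteria = failed,
             stringsAsFactors = FALSE)
}

#' Screen all trials of a sequence
#'
#' @inheritParams screen_trial
#' @param trials an `mht_trials` data frame
#' @param keep `"all"` to return every decision, `"eligible"` to keep only
#'   eligible person-trials (saves memory over long trial sequences)
#' @return stacked decisions of [screen_trial()] over all trials
#' @export
screen_trials <- function(registry, codebook, trials,
                          registration_cutoff = as.Date("2005-12-31"),
                          keep = c("all", "eligible")) {
  keep <- match.arg(keep)
  index <- eligibility_index(registry, codebook)
  out <- vector("list", nrow(trials))
  for (k in seq_len(nrow(trials))) {
    dec <- screen_trial(registry, codebook, trials[k, ],
                        registration_cutoff, index = index)
    if (keep == "eligible") dec <- dec[dec$eligible, , drop = FALSE]
    out[[k]] <- dec
  }
  do.call(rbind, out)
}
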