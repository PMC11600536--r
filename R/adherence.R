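## Treatment-episode construction and per-protocol deviation times.
##
## One fill of n_packages packages at ddd_per_package defined daily doses,
## taken at 1 DDD/day, covers n_packages * ddd_per_package days.  After each
## fill the exposure window is extended by a grace period of twice the most
## recent single package's coverage: the worked rule for a 42-tablet package
## is an 84-day extension beyond the last covered day.  Fills chain into one
## episode while each new fill arrives on or before the current extension
## end; a later fill starts a new episode.
##
## LNG-IUS insertion records are devices, not refill streams: the system is
## assumed in place for the entire follow-up, so insertions neither extend
## nor shorten an episode and only the oral component of the oral
## oestrogen + LNG-IUS strategy can trigger a discontinuation.

fill_coverage_days <- function(d)
  as.integer(d$n_packages) * as.integer(d$ddd_per_package)

## episode chain over integer dates; returns a matrix with one row per
## episode: start, covered_until, extended_until, n_fills
episode_bounds <- function(dates, cov, grace) {
  n <- length(dates)
  start <- covered <- extended <- fills <- integer(n)
  k <- 1L
  start[1L] <- dates[1L]
  covered[1L] <- dates[1L] + cov[1L] - 1L
  extended[1L] <- covered[1L] + grace[1L]
  fills[1L] <- 1L
  if (n > 1L) for (i in 2L:n) {
    if (dates[i] <= extended[k]) {
      covered[k] <- max(covered[k], dates[i] + cov[i] - 1L)
      extended[k] <- covered[k] + grace[i]
      fills[k] <- fills[k] + 1L
    } else {
      k <- k + 1L
      start[k] <- dates[i]
      covered[k] <- dates[i] + cov[i] - 1L
      extended[k] <- covered[k] + grace[i]
      fills[k] <- 1L
    }
  }
  cbind(start = start[seq_len(k)], covered_until = covered[seq_len(k)],
        extended_until = extended[seq_len(k)], n_fills = fills[seq_len(k)])
}

#' Build continuous treatment episodes from one woman's dispensations
#'
#' @param dispensations the woman's MHT dispensation records (dispensations
#'   schema), any order; `hormone_content == "none"` rows and LNG-IUS
#'   insertions are ignored
#' @return a data frame with one row per episode: `person_id`,
#'   `episode_start`, `covered_until` (last day covered by fills),
#'   `extended_until` (`covered_until` + 2 x the most recent package's
#'   coverage), `n_fills`
#' @examples
#' d <- data.frame(person_id = "w1", dispense_date = as.Date("2010-01-01"),
#'                 atc_code = "G03CA03", route = "oral",
#'                 hormone_content = "oestrogen_only", oestrogen_dose = 2,
#'                 progestogen_dose = 0, n_packages = 1L,
#'                 ddd_per_package = 42L)
#' e <- compute_episodes(d)
#' e$extended_until - e$covered_until  # 84 days
#' @export
compute_episodes <- function(dispensations) {
  d <- dispensations
  d <- d[!is.na(d$hormone_content) &
           !(d$hormone_content %in% c("none", "lng_ius")), , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(person_id = character(),
                      episode_start = as.Date(character()),
                      covered_until = as.Date(character()),
                      extended_until = as.Date(character()),
                      n_fills = integer()))
  cov <- fill_coverage_days(d)
  if (any(cov <= 0L)) stop("zero-coverage fill in dispensations", call. = FALSE)
  o <- order(d$dispense_date)
  b <- episode_bounds(as.integer(d$dispense_date)[o], cov[o],
                      2L * as.integer(d$ddd_per_package)[o])
  data.frame(person_id = d$person_id[1L],
             episode_start = as.Date(b[, "start"], origin = "1970-01-01"),
             covered_until = as.Date(b[, "covered_until"], origin = "1970-01-01"),
             extended_until = as.Date(b[, "extended_until"], origin = "1970-01-01"),
             n_fills = as.integer(b[, "n_fills"]))
}

## Which strategies is a single fill consistent with?  Used to detect
## preparation switches at the strategy level (a brand change within the
## same strategy class is not a protocol deviation).
fill_compatible_strategies <- function(route, hormone_content) {
  switch(hormone_content,
    tibolone = "tibolone",
    lng_ius = c("oral_oestrogen_lng_ius", "transdermal_combined"),
    progestogen_only = c("oral_combined_continuous", "oral_combined_sequential",
                         "transdermal_combined", "oral_oestrogen_lng_ius"),
    fixed_combined_continuous =
      if (route == "transdermal") "transdermal_combined"
      else "oral_combined_continuous",
    fixed_combined_sequential =
      if (route == "transdermal") "transdermal_combined"
      else "oral_combined_sequential",
    oestrogen_only =
      if (route == "transdermal")
        c("transdermal_combined", "transdermal_unopposed_oestrogen")
      else c("oral_combined_continuous", "oral_combined_sequential",
             "oral_unopposed_oestrogen", "oral_oestrogen_lng_ius"),
    character())
}

#' Per-protocol deviation time for one person-trial
#'
#' For an initiator the deviation day is the earlier of (i) the day the
#' baseline episode's grace extension is passed without a refill
#' (`discontinued`) and (ii) the first day she redeems a fill that is
#' incompatible with her baseline strategy (`switched_preparation`).  For a
#' non-initiator it is the day of her first systemic MHT fill during
#' follow-up (`non_initiator_started`).  Deviations are reported in days
#' since the trial start; `NA` if none occurs within `followup_days`.
#'
#' @param trial_start `Date`; first day of the person-trial's month
#' @param strategy the baseline strategy of the person-trial
#' @param dispensations the woman's MHT dispensations (all dates)
#' @param episodes output of [compute_episodes()] for the same woman (only
#'   used for initiators; computed if `NULL`)
#' @param followup_days administrative follow-up (default 730)
#' @return a one-row data frame `deviation_day` (integer days since trial
#'   start or `NA`) and `reason`
#' @export
pp_censor_time <- function(trial_start, strategy, dispensations,
                           episodes = NULL, followup_days = 730L) {
  s <- as.Date(trial_start)
  end <- s + followup_days
  d <- dispensations[!is.na(dispensations$hormone_content) &
                       dispensations$hormone_content != "none", , drop = FALSE]
  if (strategy == "non_initiator") {
    fu <- d$dispense_date[d$dispense_date > s & d$dispense_date <= end]
    dev <- if (length(fu)) as.integer(min(fu) - s) else NA_integer_
    return(data.frame(deviation_day = dev,
                      reason = if (is.na(dev)) NA_character_
                      else "non_initiator_started"))
  }
  if (is.null(episodes)) episodes <- compute_episodes(d)
  ## baseline episode: exposure window overlapping the trial month
  base <- episodes[episodes$extended_until >= s &
                     episodes$episode_start < add_months(s, 1L), , drop = FALSE]
  if (nrow(base) == 0L)
    stop("pp_censor_time: initiator has no baseline episode", call. = FALSE)
  base <- base[1L, ]
  disc <- if (base$extended_until < end)
    as.integer(base$extended_until - s) + 1L else NA_integer_
  sw <- NA_integer_
  fu <- d[d$dispense_date > s & d$dispense_date <= end, , drop = FALSE]
  if (nrow(fu)) {
    ok <- vapply(seq_len(nrow(fu)), function(i)
      strategy %in% fill_compatible_strategies(fu$route[i],
                                               fu$hormone_content[i]),
      logical(1))
    if (any(!ok)) sw <- as.integer(min(fu$dispense_date[!ok]) - s)
  }
  dev <- suppressWarnings(min(disc, sw, na.rm = TRUE))
  if (!is.finite(dev))
    return(data.frame(deviation_day = NA_integer_, reason = NA_character_))
  reason <- if (!is.na(sw) && (is.na(disc) || sw <= disc))
    "switched_preparation" else "discontinued"
  data.frame(deviation_day = as.integer(dev), reason = reason)
}

#' Per-protocol deviations for a stacked person-trial table
#'
#' Vectorised equivalent of applying [pp_censor_time()] to every
#' person-trial row.
#'
#' @param person_trials output of [build_person_trials()]
#' @param registry an `mht_registry`
#' @param followup_days administrative follow-up
#' @return `person_trials` key columns plus `deviation_day`, `reason`
#' @export
compute_deviations <- function(person_trials, registry,
                               followup_days = 730L) {
  pt <- person_trials
  d <- registry$dispensations
  d <- d[!is.na(d$hormone_content) & d$hormone_content != "none", ,
         drop = FALSE]
  n <- nrow(pt)
  dev <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  s <- as.integer(as.Date(pt$trial_start))
  end <- s + as.integer(followup_days)
  dd <- as.integer(d$dispense_date)

  ## --- non-initiators: first systemic MHT fill after the trial start ----
  ni <- pt$strategy == "non_initiator"
  if (any(ni)) {
    first_fill <- tapply(dd, d$person_id, min)
    f <- as.integer(first_fill[pt$person_id[ni]])
    hit <- !is.na(f) & f > s[ni] & f <= end[ni]
    ## a first-ever fill before the trial start cannot happen for an
    ## eligible non-initiator (washout); later fills are what we seek
    late <- !is.na(f) & f <= s[ni]
    if (any(late)) {
      ## woman had fills before this trial (prior-use washout already
      ## elapsed); fall back to a per-person search
      idx <- which(ni)[late]
      for (i in idx) {
        fu <- dd[d$person_id == pt$person_id[i] & dd > s[i] & dd <= end[i]]
        if (length(fu)) { dev[i] <- min(fu) - s[i]; reason[i] <- "non_initiator_started" }
      }
    }
    dev[which(ni)[hit]] <- f[hit] - s[ni][hit]
    reason[which(ni)[hit]] <- "non_initiator_started"
  }

  ## --- initiators ------------------------------------------------------
  init_rows <- which(!ni)
  if (length(init_rows)) {
    keep <- d[d$person_id %in% unique(pt$person_id[init_rows]), , drop = FALSE]
    keep <- keep[order(keep$person_id, keep$dispense_date), , drop = FALSE]
    by_person <- split(seq_len(nrow(keep)), keep$person_id)
    for (i in init_rows) {
      rows <- by_person[[pt$person_id[i]]]
      di <- keep[rows, , drop = FALSE]
      r <- pp_censor_time(as.Date(s[i], origin = "1970-01-01"),
                          pt$strategy[i], di, NULL, followup_days)
      dev[i] <- r$deviation_day
      reason[i] <- r$reason
    }
  }
  cbind(pt[c("person_id", "trial_index", "strategy")],
        deviation_day = dev, reason = reason,
        stringsAsFactors = FALSE)
}
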