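## Eight-arm treatment strategy classification from trial-month
## dispensations.

STRATEGY_LEVELS <- c("oral_combined_continuous", "oral_combined_sequential",
                     "oral_unopposed_oestrogen", "oral_oestrogen_lng_ius",
                     "tibolone", "transdermal_combined",
                     "transdermal_unopposed_oestrogen", "non_initiator")
INITIATOR_STRATEGIES <- setdiff(STRATEGY_LEVELS, "non_initiator")

#' Strategy classification rule parameters
#'
#' The oestrogen:progestogen per-DDD dose ratio separates the two
#' self-combined oral therapies: below `ratio_threshold` (7) the pair is
#' classified continuous combined, above it sequential combined.  A ratio of
#' exactly 7 is not covered by the published rule; the tie policy assigns it
#' to the continuous class.
#'
#' @param ratio_threshold positive number, default 7
#' @param tie_policy what to do at a ratio of exactly the threshold
#' @return a list of class `mht_strategy_rule`
#' @export
strategy_rule <- function(ratio_threshold = 7,
                          tie_policy = c("continuous_on_tie")) {
  stopifnot(is.numeric(ratio_threshold), ratio_threshold > 0)
  structure(list(ratio_threshold = ratio_threshold,
                 tie_policy = match.arg(tie_policy)),
            class = "mht_strategy_rule")
}

#' Classify one woman's trial-month dispensations into a treatment strategy
#'
#' Decision procedure, applied in order: (1) no MHT records: non-initiator;
#' (2) any tibolone: tibolone; (3) transdermal oestrogen together with any
#' progestogen (oral, transdermal, or local including the levonorgestrel
#' intrauterine system), or a fixed transdermal combined product:
#' transdermal combined; (4) transdermal oestrogen alone: transdermal
#' unopposed oestrogen; (5) oral oestrogen plus an LNG-IUS insertion: oral
#' oestrogen + LNG-IUS; (6) a fixed oral combined product: its labelled
#' continuous/sequential class; (7) oral oestrogen plus a separate
#' progestogen (self-combined): by the per-DDD dose ratio against the rule's
#' threshold; (8) oral oestrogen alone: oral unopposed oestrogen.
#' Progestogen-only dispensations with no oestrogen and no tibolone are not
#' systemic MHT initiation: the woman is classified non-initiator and the
#' record logged as an anomaly (attribute `anomaly`).
#'
#' @param dispensations a data frame of the woman's dispensation records in
#'   the trial month (dispensations schema; non-MHT rows are ignored)
#' @param rule an [strategy_rule()]
#' @return a length-1 character strategy, with attribute `rule_fired`
#' @export
assign_strategy <- function(dispensations, rule = strategy_rule()) {
  d <- dispensations
  d <- d[!is.na(d$hormone_content) & d$hormone_content != "none", ,
         drop = FALSE]
  res <- function(strategy, rule_fired, anomaly = FALSE) {
    structure(strategy, rule_fired = rule_fired, anomaly = anomaly)
  }
  if (nrow(d) == 0L) return(res("non_initiator", "no_mht_records"))
  if (any(d$hormone_content == "tibolone"))
    return(res("tibolone", "tibolone"))
  td_oe <- d$route == "transdermal" &
    d$hormone_content %in% c("oestrogen_only", "fixed_combined_continuous",
                             "fixed_combined_sequential")
  any_prog <- d$hormone_content %in% c("progestogen_only", "lng_ius")
  td_fixed <- d$route == "transdermal" &
    d$hormone_content %in% c("fixed_combined_continuous",
                             "fixed_combined_sequential")
  if (any(td_fixed) || (any(td_oe) && any(any_prog)))
    return(res("transdermal_combined", "transdermal_combined"))
  if (any(td_oe)) return(res("transdermal_unopposed_oestrogen",
                             "transdermal_unopposed"))
  oral_oe <- d$route == "oral" & d$hormone_content == "oestrogen_only"
  if (any(oral_oe) && any(d$hormone_content == "lng_ius"))
    return(res("oral_oestrogen_lng_ius", "oral_oestrogen_lng_ius"))
  fixed_oral <- d$route == "oral" &
    d$hormone_content %in% c("fixed_combined_continuous",
                             "fixed_combined_sequential")
  if (any(fixed_oral)) {
    lab <- d$hormone_content[fixed_oral][1L]
    return(res(if (lab == "fixed_combined_continuous")
      "oral_combined_continuous" else "oral_combined_sequential",
      "fixed_oral_combined"))
  }
  sep_prog <- d$hormone_content == "progestogen_only"
  if (any(oral_oe) && any(sep_prog)) {
    e <- sum(d$oestrogen_dose[oral_oe])
    p <- sum(d$progestogen_dose[sep_prog])
    if (p <= 0) return(res("oral_unopposed_oestrogen",
                           "self_combined_zero_progestogen", anomaly = TRUE))
    ratio <- e / p
    if (ratio < rule$ratio_threshold)
      return(res("oral_combined_continuous", "self_combined_ratio_lt"))
    if (ratio > rule$ratio_threshold)
      return(res("oral_combined_sequential", "self_combined_ratio_gt"))
    return(res("oral_combined_continuous", "self_combined_ratio_tie",
               anomaly = TRUE))
  }
  if (any(oral_oe)) return(res("oral_unopposed_oestrogen", "oral_unopposed"))
  ## progestogen-only (or LNG-IUS alone): not systemic MHT initiation
  res("non_initiator", "progestogen_only_anomaly", anomaly = TRUE)
}

#' Classify every eligible woman for every trial
#'
#' Applies [assign_strategy()] per (woman, trial) to the dispensations
#' redeemed inside each trial month.
#'
#' @param eligibility decisions from [screen_trials()] (only eligible rows
#'   are classified)
#' @param registry an `mht_registry`
#' @param trials an `mht_trials` data frame
#' @param rule an [strategy_rule()]
#' @return a data frame `person_id`, `trial_index`, `strategy`, `rule_fired`
#' @export
assign_strategies <- function(eligibility, registry, trials,
                              rule = strategy_rule()) {
  d <- registry$dispensations
  d <- d[!is.na(d$hormone_content) & d$hormone_content != "none", ,
         drop = FALSE]
  out <- vector("list", nrow(trials))
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    elig <- eligibility[eligibility$trial_index == tr$trial_index &
                          eligibility$eligible, "person_id"]
    if (!length(elig)) next
    s <- as.Date(tr$start_date)
    e <- add_months(s, 1L)
    dm <- d[d$dispense_date >= s & d$dispense_date < e &
              d$person_id %in% elig, , drop = FALSE]
    strategy <- rep("non_initiator", length(elig))
    fired <- rep("no_mht_records", length(elig))
    if (nrow(dm)) {
      by_person <- split(seq_len(nrow(dm)), dm$person_id)
      j <- match(names(by_person), elig)
      for (i in seq_along(by_person)) {
        a <- assign_strategy(dm[by_person[[i]], , drop = FALSE], rule)
        strategy[j[i]] <- as.character(a)
        fired[j[i]] <- attr(a, "rule_fired")
      }
    }
    out[[k]] <- data.frame(person_id = elig, trial_index = tr$trial_index,
                           strategy = strategy, rule_fired = fired,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(person_id = character(), trial_index = integer(),
                      strategy = character(), rule_fired = character())
  res
}
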