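## End-to-end pipeline driver: screen -> assign -> build -> adherence ->
## weights -> estimate, with per-stage accounting.

#' Run the full nested-trial emulation on a registry
#'
#' Drives the whole analysis: builds the monthly trial sequence over the
#' study window, screens eligibility (age 50-58, MHT washout, lifetime
#' exclusions), classifies each eligible woman's trial-month dispensations
#' into one of the eight strategies, stacks person-trials with
#' cause-specific outcome ascertainment, derives per-protocol deviations
#' and censoring weights where requested, and fits the requested weighted
#' models per contrast, outcome and analysis.
#'
#' @param registry an `mht_registry`
#' @param codebook an `mht_codebook`
#' @param study_start,study_end month-aligned study window
#' @param washout_days 730 (default) or 2190 for the six-year sensitivity
#' @param followup_days administrative follow-up per trial
#' @param contrasts initiator strategies to contrast against non-initiators
#'   (default: every strategy present among the assignments)
#' @param outcomes outcome ids (default all five)
#' @param analyses subset of `c("itt", "pp")`
#' @param models subset of `c("cause_specific", "fine_gray")`
#' @param covariates propensity/censoring model covariates
#' @param truncate optional weight-truncation probabilities, see
#'   [fit_iptw()]
#' @param vte_competes see [build_person_trials()]
#' @return an object of class `mht_emulation`: the results table
#'   (`$results`), fitted `mht_estimate`s (`$estimates`), the stacked
#'   person-trials, the per-trial accounting (`$trial_summary`) and the
#'   call
#' @export
emulate_trials <- function(registry, codebook = default_codebook(),
                           study_start = as.Date("2007-07-01"),
                           study_end = as.Date("2018-12-01"),
                           washout_days = 730L, followup_days = 730L,
                           contrasts = NULL, outcomes = OUTCOMES,
                           analyses = c("itt", "pp"),
                           models = "cause_specific",
                           covariates = DEFAULT_COVARIATES,
                           truncate = NULL, vte_competes = TRUE) {
  analyses <- match.arg(analyses, c("itt", "pp"), several.ok = TRUE)
  models <- match.arg(models, c("cause_specific", "fine_gray"),
                      several.ok = TRUE)
  trials <- make_trial_sequence(study_start, study_end, washout_days,
                                followup_days)
  eligibility <- screen_trials(registry, codebook, trials, keep = "eligible")
  assignments <- assign_strategies(eligibility, registry, trials)
  pt <- build_person_trials(eligibility, assignments, registry, codebook,
                            trials, outcomes, vte_competes = vte_competes)

  ## per-trial accounting (participants, initiators, composite events)
  ts <- do.call(rbind, lapply(split(pt, pt$trial_index), function(d)
    data.frame(trial_index = d$trial_index[1L], participants = nrow(d),
               initiators = sum(d$initiator),
               events_composite = sum(d$status_composite_cvd == "event"))))
  rownames(ts) <- NULL

  deviations <- NULL
  if ("pp" %in% analyses)
    deviations <- compute_deviations(pt, registry, followup_days)

  if (is.null(contrasts))
    contrasts <- intersect(INITIATOR_STRATEGIES, unique(pt$strategy))
  estimates <- list()
  rows <- list()
  for (ct in contrasts) {
    wdat <- fit_iptw(pt, ct, covariates, truncate)
    pp_dat <- NULL
    if ("pp" %in% analyses)
      pp_dat <- apply_pp_censoring(wdat, deviations, outcomes)
    for (oo in outcomes) {
      for (an in analyses) {
        for (md in models) {
          est <- if (md == "cause_specific") {
            if (an == "itt") fit_cause_specific(wdat, oo, "itt")
            else fit_cause_specific(fit_ipcw(pp_dat, oo, covariates), oo, "pp")
          } else {
            fit_fine_gray(if (an == "itt") wdat else pp_dat, oo, an)
          }
          key <- paste(ct, oo, an, md, sep = ".")
          estimates[[key]] <- est
          rows[[key]] <- data.frame(
            contrast = ct, outcome = oo, analysis = an, model = md,
            hr = est$hr, ci_low = est$ci95[1L], ci_high = est$ci95[2L],
            log_hr = est$log_hr, se_robust = est$se_robust,
            n_events = est$n_events, person_years = est$person_years,
            inestimable = est$inestimable, stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, estimates = estimates,
                 person_trials = pt, trial_summary = ts,
                 deviations = deviations, trials = trials,
                 call = match.call()),
            class = "mht_emulation")
}

#' @export
print.mht_emulation <- function(x, ...) {
  cat(sprintf("Emulated sequence of %d monthly trials\n", nrow(x$trials)))
  cat(sprintf("  %d person-trials (%d initiator), %d women\n",
              nrow(x$person_trials), sum(x$person_trials$initiator),
              length(unique(x$person_trials$person_id))))
  cat("  hazard ratio estimates:\n")
  r <- x$results
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-32s %-20s %-3s %-14s %s\n", r$contrast[i], r$outcome[i],
                r$analysis[i], r$model[i],
                if (r$inestimable[i]) "inestimable"
                else sprintf("HR %.2f (%.2f to %.2f)", r$hr[i], r$ci_low[i],
                             r$ci_high[i])))
  invisible(x)
}

#' @export
summary.mht_emulation <- function(object, ...) {
  cat("Trial-level accounting (first and last 3 trials):\n")
  ts <- object$trial_summary
  show <- unique(c(utils::head(seq_len(nrow(ts)), 3L),
                   utils::tail(seq_len(nrow(ts)), 3L)))
  print(ts[show, ], row.names = FALSE)
  cat("\n")
  print(object)
  invisible(object)
}

#' @export
coef.mht_emulation <- function(object, ...) {
  r <- object$results
  stats::setNames(r$log_hr, paste(r$contrast, r$outcome, r$analysis,
                                  r$model, sep = "."))
}

#' @export
plot.mht_emulation <- function(x, outcome = "composite_cvd",
                               contrast = NULL, ...) {
  ct <- contrast %||% x$results$contrast[1L]
  wdat <- fit_iptw(x$person_trials, ct)
  inc <- adjusted_incidence(wdat, outcome)
  plot(inc, ...)
  invisible(inc)
}
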