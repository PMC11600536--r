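## Weighted cause-specific Cox and Fine-Gray estimation with
## cluster-robust variance, adjusted cumulative incidence and adjusted
## incidence rates.
##
## Marginal structural form: confounding is handled entirely through the
## weights; the hazard model contains a single time-fixed binary treatment
## term.  Ties use the Efron approximation; the variance is the sandwich
## estimator clustered on person identity, because women recur across the
## stacked trials.

new_estimate <- function(contrast, outcome, analysis, model, log_hr, se,
                         n, n_events, person_years, inestimable = FALSE) {
  structure(list(contrast = contrast, outcome = outcome, analysis = analysis,
                 model = model, log_hr = log_hr, hr = exp(log_hr),
                 se_robust = se,
                 ci95 = exp(log_hr + c(-1, 1) * 1.96 * se),
                 alpha = 0.05, n = n, n_events = n_events,
                 person_years = person_years, inestimable = inestimable),
            class = "mht_estimate")
}

#' @export
print.mht_estimate <- function(x, ...) {
  cat(sprintf("%s %s, %s analysis (%s)\n", x$contrast, "vs non_initiator",
              x$analysis, x$model))
  if (x$inestimable) {
    cat("  inestimable: zero events in one arm\n")
    return(invisible(x))
  }
  cat(sprintf("  HR %.2f (95%% CI %.2f to %.2f), outcome %s\n",
              x$hr, x$ci95[1L], x$ci95[2L], x$outcome))
  cat(sprintf("  events %d, person-years %.0f, rows %d\n",
              x$n_events, x$person_years, x$n))
  invisible(x)
}

#' @export
coef.mht_estimate <- function(object, ...) {
  stats::setNames(object$log_hr, "initiator")
}

#' @export
vcov.mht_estimate <- function(object, ...) {
  matrix(object$se_robust^2, 1L, 1L,
         dimnames = list("initiator", "initiator"))
}

#' @export
confint.mht_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  matrix(object$log_hr + c(-1, 1) * z * object$se_robust, 1L, 2L,
         dimnames = list("initiator",
                         sprintf("%.1f %%", c((1 - level) / 2,
                                              1 - (1 - level) / 2) * 100)))
}

#' @export
summary.mht_estimate <- function(object, ...) {
  print(object)
  invisible(object)
}

estimate_frame <- function(data, outcome, analysis) {
  if (analysis == "pp" && !is.null(data$tstart)) {
    ## interval-expanded per-protocol data from fit_ipcw
    data.frame(tstart = data$tstart, tstop = data$tstop,
               ev = data$event == 1L, trt = as.integer(data$initiator),
               w = data$weight %||% data$sw, id = data$person_id,
               stringsAsFactors = FALSE)
  } else {
    tc <- paste0("time_", outcome)
    sc <- paste0("status_", outcome)
    if (is.null(data[[tc]]))
      stop("data has no follow-up columns for outcome ", outcome,
           call. = FALSE)
    w <- data$sw %||% rep(1, nrow(data))
    data.frame(time = data[[tc]], ev = data[[sc]] == "event",
               trt = as.integer(data$initiator), w = w,
               id = data$person_id, status = data[[sc]],
               stringsAsFactors = FALSE)
  }
}

#' Weighted cause-specific Cox model for one contrast and outcome
#'
#' Maximises the weighted Efron partial likelihood of a proportional
#' hazards model with a single binary treatment term on the stacked
#' person-trials of one contrast (competing events are already censored by
#' the cause-specific ascertainment of [build_person_trials()]).  The
#' reported variance is the robust sandwich estimator with clustering on
#' `person_id`.  Intention-to-treat data are one row per person-trial;
#' per-protocol data may be the interval-expanded output of [fit_ipcw()]
#' (detected by its `tstart` column), in which case the cumulative combined
#' weight per interval is used.
#'
#' @param data a weighted contrast dataset ([fit_iptw()], optionally
#'   [apply_pp_censoring()] + [fit_ipcw()])
#' @param outcome outcome id
#' @param analysis `"itt"` or `"pp"`
#' @return an object of class `mht_estimate`
#' @export
fit_cause_specific <- function(data, outcome, analysis = c("itt", "pp")) {
  analysis <- match.arg(analysis)
  df <- estimate_frame(data, outcome, analysis)
  ev_by_arm <- tapply(df$ev, df$trt, sum)
  contrast <- attr(data, "contrast") %||%
    setdiff(unique(data$strategy), "non_initiator")[1L] %||% "initiator"
  py <- if (!is.null(df$time)) sum(df$time) / 365.25
  else sum(df$tstop - df$tstart) / 365.25
  if (length(ev_by_arm) < 2L || any(ev_by_arm == 0L))
    return(new_estimate(contrast, outcome, analysis, "cause_specific",
                        NA_real_, NA_real_, nrow(df), sum(df$ev), py,
                        inestimable = TRUE))
  fit <- if (!is.null(df$time))
    survival::coxph(survival::Surv(time, ev) ~ trt, data = df,
                    weights = w, cluster = id, ties = "efron", robust = TRUE)
  else
    survival::coxph(survival::Surv(tstart, tstop, ev) ~ trt, data = df,
                    weights = w, cluster = id, ties = "efron", robust = TRUE)
  new_estimate(contrast, outcome, analysis, "cause_specific",
               unname(stats::coef(fit)["trt"]),
               sqrt(diag(fit$var))[[1L]],
               nrow(df), sum(df$ev), py)
}

#' Weighted Fine-Gray subdistribution hazard model
#'
#' Sensitivity companion to [fit_cause_specific()]: individuals who die or
#' experience a competing event remain in the risk set with
#' time-decreasing census weights (the `finegray` data expansion), giving
#' a subdistribution hazard ratio, i.e. a total effect on cumulative
#' incidence.  With zero competing events the expansion is the identity
#' and the subdistribution estimate equals the cause-specific one.  Takes
#' single-row data; for a per-protocol run pass data already censored by
#' [apply_pp_censoring()].
#'
#' @inheritParams fit_cause_specific
#' @return an object of class `mht_estimate`
#' @export
fit_fine_gray <- function(data, outcome, analysis = c("itt", "pp")) {
  analysis <- match.arg(analysis)
  if (!is.null(data$tstart))
    stop("fit_fine_gray expects single-row (non interval-expanded) data",
         call. = FALSE)
  df <- estimate_frame(data, outcome, analysis)
  contrast <- attr(data, "contrast") %||%
    setdiff(unique(data$strategy), "non_initiator")[1L] %||% "initiator"
  py <- sum(df$time) / 365.25
  ev_by_arm <- tapply(df$ev, df$trt, sum)
  if (length(ev_by_arm) < 2L || any(ev_by_arm == 0L))
    return(new_estimate(contrast, outcome, analysis, "fine_gray",
                        NA_real_, NA_real_, nrow(df), sum(df$ev), py,
                        inestimable = TRUE))
  df$fstat <- factor(ifelse(df$ev, "event",
                            ifelse(df$status %in% c("competing_event", "death"),
                                   "competing", "censor")),
                     levels = c("censor", "event", "competing"))
  df$row_id <- seq_len(nrow(df))
  df2 <- df[c("time", "fstat", "trt", "w", "id", "row_id")]
  fg <- survival::finegray(survival::Surv(time, fstat) ~ trt + w + id,
                           data = df2, etype = "event", id = row_id,
                           timefix = FALSE)
  fit <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ trt, data = fg,
    weights = fgwt * w, cluster = id, ties = "efron", robust = TRUE)
  new_estimate(contrast, outcome, analysis, "fine_gray",
               unname(stats::coef(fit)["trt"]),
               sqrt(diag(fit$var))[[1L]],
               nrow(df), sum(df$ev), py)
}

#' Adjusted cumulative incidence curves and one-year risk difference
#'
#' IPTW-weighted nonparametric (Aalen-Johansen) cumulative incidence of
#' the outcome per arm on a daily grid, treating death and competing
#' events as competing states and emigration/administrative end as
#' censoring.  The one-year absolute risk difference contrasts each
#' initiator arm with the non-initiator arm at day 365.
#'
#' @param data weighted single-row contrast data ([fit_iptw()])
#' @param outcome outcome id
#' @param times evaluation grid in days (default 0..730)
#' @return object of class `mht_incidence`: `times`, a `cif` matrix (arm x
#'   time), and `risk_difference_1y`
#' @export
adjusted_incidence <- function(data, outcome, times = 0:730) {
  df <- estimate_frame(data, outcome, "itt")
  df$arm <- ifelse(df$trt == 1L,
                   attr(data, "contrast") %||% "initiator", "non_initiator")
  arms <- unique(df$arm)
  if (!("non_initiator" %in% arms))
    stop("non_initiator arm absent from data", call. = FALSE)
  df$fstat <- factor(ifelse(df$ev, "event",
                            ifelse(df$status %in% c("competing_event", "death"),
                                   "competing", "censor")),
                     levels = c("censor", "event", "competing"))
  cif <- matrix(0, length(arms), length(times),
                dimnames = list(arms, NULL))
  for (arm in arms) {
    sub <- df[df$arm == arm, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(time, fstat) ~ 1, data = sub,
                             weights = w, timefix = FALSE)
    st <- which(fit$states == "event")
    sm <- summary(fit, times = times, extend = TRUE)
    cif[arm, ] <- sm$pstate[, st]
  }
  rd <- cif[, which.min(abs(times - 365)), drop = TRUE] -
    cif["non_initiator", which.min(abs(times - 365))]
  structure(list(outcome = outcome, times = times, cif = cif,
                 risk_difference_1y = rd[setdiff(arms, "non_initiator")]),
            class = "mht_incidence")
}

#' @export
print.mht_incidence <- function(x, ...) {
  cat(sprintf("Adjusted cumulative incidence, outcome %s\n", x$outcome))
  at <- which.min(abs(x$times - 365))
  for (arm in rownames(x$cif))
    cat(sprintf("  %-32s 1-year incidence %.5f\n", arm, x$cif[arm, at]))
  for (arm in names(x$risk_difference_1y))
    cat(sprintf("  1-year risk difference (%s vs non_initiator): %.5f\n",
                arm, x$risk_difference_1y[[arm]]))
  invisible(x)
}

#' @export
plot.mht_incidence <- function(x, ...) {
  graphics::matplot(x$times, t(x$cif), type = "l", lty = 1,
                    xlab = "days since trial start",
                    ylab = "adjusted cumulative incidence",
                    main = x$outcome, ...)
  graphics::legend("topleft", legend = rownames(x$cif), lty = 1,
                   col = seq_len(nrow(x$cif)), bty = "n")
  invisible(x)
}

#' Adjusted incidence rates per arm and follow-up window
#'
#' Weighted events divided by weighted person-years, scaled to events per
#' 1000 person-years, per arm and follow-up period.  Scale-invariant in
#' the weights.
#'
#' @param data weighted single-row contrast data
#' @param outcome outcome id
#' @param periods list of `c(lo, hi)` day windows (default the full
#'   follow-up)
#' @return data frame `arm`, `period`, `events` (weighted),
#'   `person_years` (weighted), `rate_per_1000py`
#' @export
adjusted_rates <- function(data, outcome, periods = list(c(0, 730))) {
  df <- estimate_frame(data, outcome, "itt")
  df$arm <- ifelse(df$trt == 1L,
                   attr(data, "contrast") %||% "initiator", "non_initiator")
  out <- list()
  for (p in periods) {
    lo <- p[1L]; hi <- p[2L]
    at_risk <- df$time > lo
    expo <- pmax(0, pmin(df$time, hi) - lo)
    for (arm in unique(df$arm)) {
      g <- df$arm == arm
      wev <- sum(df$w[g & at_risk & df$ev & df$time <= hi])
      wpy <- sum((df$w * expo)[g]) / 365.25
      out[[length(out) + 1L]] <- data.frame(
        arm = arm, period = sprintf("(%d,%d]", lo, hi),
        events = wev, person_years = wpy,
        rate_per_1000py = if (wpy > 0) wev / wpy * 1000 else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
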