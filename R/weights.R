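## Stabilized inverse-probability weights: treatment weights (IPTW) for
## confounding, censoring weights (IPCW) for the selection induced by
## artificial per-protocol censoring.

DEFAULT_COVARIATES <- c("age", "trial_month", "calendar_year", "education",
                        "geo_region", "region_of_birth", "med_hypertension",
                        "med_heart_disease", "med_diabetes")

## Binomial Fisher scoring on a pre-built design matrix.  Numerically the
## same IRLS as glm.fit but solving the normal equations with BLAS
## crossprod, which matters on interval-expanded data with hundreds of
## thousands of rows; falls back to glm.fit if the information matrix is
## ill-conditioned.
fast_logit_fit <- function(x, y, start = NULL, maxit = 25L, tol = 1e-6) {
  beta <- start %||% {
    b <- numeric(ncol(x))
    b[1L] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
    b
  }
  eta <- drop(x %*% beta)
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    p <- stats::plogis(eta)
    wt <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / wt
    xw <- x * wt
    upd <- tryCatch(solve(crossprod(xw, x), crossprod(xw, z)),
                    error = function(e) NULL)
    if (is.null(upd)) {
      f <- suppressWarnings(stats::glm.fit(x, y,
                                           family = stats::binomial()))
      return(list(prob = f$fitted.values, beta = f$coefficients))
    }
    beta <- drop(upd)
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12)))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  list(prob = stats::plogis(eta), beta = beta)
}

## keep only covariates with variation; factors gain explicit factor() in
## the formula so character columns model cleanly
covariate_terms <- function(data, covariates) {
  keep <- character()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) stop("unknown covariate: ", cv, call. = FALSE)
    if (length(unique(x)) < 2L) next
    keep <- c(keep, if (is.character(x)) sprintf("factor(%s)", cv) else cv)
  }
  keep
}

#' Stabilized inverse probability of treatment weights
#'
#' Restricts the stacked person-trials to one contrast (a single initiator
#' strategy versus non-initiators), fits a binomial logistic propensity
#' model of initiation on the baseline covariates, and attaches stabilized
#' weights `sw = P(A = a) / P(A = a | L)` with the marginal arm probability
#' in the numerator.  Within a contrast the mean stabilized weight is
#' approximately 1; large deviations indicate model trouble (see
#' [weight_diagnostics()]).
#'
#' @param person_trials output of [build_person_trials()]
#' @param contrast an initiator strategy name
#' @param covariates baseline covariate columns (default: age, trial month,
#'   calendar year, education, geographical region, region of birth, and
#'   the three medication flags, continuous terms entering linearly)
#' @param truncate `NULL` (default, no truncation) or two probabilities,
#'   e.g. `c(0.01, 0.99)`, at whose weight quantiles the weights are capped
#' @return the contrast-restricted person-trials with columns `propensity`
#'   and `sw`; attributes `contrast` and `propensity_coef`
#' @export
fit_iptw <- function(person_trials, contrast,
                     covariates = DEFAULT_COVARIATES, truncate = NULL) {
  if (!(contrast %in% INITIATOR_STRATEGIES))
    stop("contrast must be an initiator strategy", call. = FALSE)
  dat <- person_trials[person_trials$strategy %in%
                         c(contrast, "non_initiator"), , drop = FALSE]
  if (!nrow(dat)) stop("no rows in contrast ", contrast, call. = FALSE)
  a <- as.integer(dat$strategy == contrast)
  if (all(a == 0L) || all(a == 1L))
    stop("contrast ", contrast, " has an empty arm", call. = FALSE)
  terms <- covariate_terms(dat, covariates)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  dat$.a <- a
  fit <- stats::glm(stats::as.formula(paste(".a ~", rhs)), data = dat,
                    family = stats::binomial())
  p <- stats::fitted(fit)
  eps <- 1e-10
  ## positivity: a treated woman with fitted propensity 0, or an untreated
  ## woman with fitted propensity 1, has no counterfactual support.
  ## (A sparse stratum of untreated women with p ~ 0 is harmless: its
  ## weights are bounded.)
  bad <- (a == 1L & p < eps) | (a == 0L & p > 1 - eps)
  if (any(bad)) {
    stop(sprintf(paste0("non-overlap: %d person-trials with fitted ",
                        "propensity 0 or 1 (first rows: %s)"),
                 sum(bad),
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  soft <- p < eps | p > 1 - eps
  if (any(soft))
    warning(sprintf(paste0("%d person-trials lie in strata with only one ",
                           "arm represented (fitted propensity 0 or 1); ",
                           "their weights are bounded but the stratum has ",
                           "no counterfactual support"), sum(soft)),
            call. = FALSE)
  pa <- mean(a)
  sw <- ifelse(a == 1L, pa / p, (1 - pa) / (1 - p))
  if (!is.null(truncate)) {
    q <- stats::quantile(sw, truncate)
    sw <- pmin(pmax(sw, q[1L]), q[2L])
  }
  dat$.a <- NULL
  dat$propensity <- p
  dat$sw <- sw
  attr(dat, "contrast") <- contrast
  attr(dat, "propensity_coef") <- stats::coef(fit)
  dat
}

#' Apply per-protocol artificial censoring to a person-trial table
#'
#' Joins the protocol-deviation times of [compute_deviations()] to the
#' stacked person-trials and, for every outcome, censors follow-up at the
#' deviation day (`status = "pp_censored"`) when the deviation precedes the
#' outcome's terminal time.
#'
#' @param person_trials output of [build_person_trials()] (possibly already
#'   weighted by [fit_iptw()])
#' @param deviations output of [compute_deviations()]
#' @param outcomes outcomes whose follow-up columns are censored
#' @return `person_trials` with adjusted `time_*`/`status_*` and a
#'   `deviation_day` column
#' @export
apply_pp_censoring <- function(person_trials, deviations,
                               outcomes = OUTCOMES) {
  key <- paste(person_trials$person_id, person_trials$trial_index)
  j <- match(key, paste(deviations$person_id, deviations$trial_index))
  if (anyNA(j))
    stop("deviations are missing for some person-trials", call. = FALSE)
  dev <- deviations$deviation_day[j]
  out <- person_trials
  out$deviation_day <- dev
  for (oo in outcomes) {
    tc <- paste0("time_", oo)
    sc <- paste0("status_", oo)
    if (is.null(out[[tc]])) next
    hit <- !is.na(dev) & dev < out[[tc]]
    out[[tc]][hit] <- dev[hit]
    out[[sc]][hit] <- "pp_censored"
  }
  out
}

#' Stabilized inverse probability of censoring weights
#'
#' Splits per-protocol follow-up into fixed-length intervals and fits
#' pooled binomial models of remaining free of protocol deviation per
#' interval: the denominator conditions on the baseline covariates (plus
#' any supplied time-varying columns), the numerator on the interval terms
#' only.  The stabilized weight for an interval is the cumulative product
#' of the numerator-to-denominator conditional probabilities of remaining
#' undeviated, and multiplies the treatment weight.  If the data contain no
#' deviations at all, every censoring weight is exactly 1.
#'
#' @param pp_data contrast-restricted, IPTW-weighted person-trials already
#'   censored by [apply_pp_censoring()] (must carry `sw` and
#'   `deviation_day`)
#' @param outcome the outcome whose follow-up defines the risk window
#' @param covariates denominator covariates
#' @param interval_days interval length (default 30)
#' @param truncate `NULL` (default) or two probabilities, e.g.
#'   `c(0.01, 0.99)`: the cumulative censoring weights are capped at those
#'   quantiles.  The cumulative product amplifies denominator-model noise
#'   for long-adhering women with high modelled stopping probability, so
#'   percentile truncation is the standard tail control under strong
#'   informative censoring
#' @return an interval-expanded data frame (class `data.frame`) with
#'   columns `tstart`, `tstop`, `event` (outcome event in the interval),
#'   `sw`, `sw_cens` (cumulative stabilized censoring weight) and `weight =
#'   sw * sw_cens`
#' @export
fit_ipcw <- function(pp_data, outcome = "composite_cvd",
                     covariates = DEFAULT_COVARIATES, interval_days = 30L,
                     truncate = NULL) {
  tc <- paste0("time_", outcome)
  sc <- paste0("status_", outcome)
  stopifnot(!is.null(pp_data[[tc]]), !is.null(pp_data$deviation_day))
  n <- nrow(pp_data)
  time <- pp_data[[tc]]
  status <- pp_data[[sc]]
  ## follow-up (post pp-censoring) per row; intervals 1..L cover (0, time]
  L <- pmax(1L, as.integer(ceiling(time / interval_days)))
  idx <- rep.int(seq_len(n), L)
  k <- sequence(L)
  cols <- c("person_id", "trial_index", "strategy", "initiator",
            intersect(covariates, names(pp_data)), "sw")
  long <- as.data.frame(lapply(pp_data[cols], function(x) x[idx]),
                        stringsAsFactors = FALSE)
  long$interval <- k
  long$tstart <- (k - 1L) * interval_days
  long$tstop <- pmin(k * interval_days, time[idx])
  last <- k == L[idx]
  long$deviate <- as.integer(last & status[idx] == "pp_censored")
  long$event <- as.integer(last & status[idx] == "event")

  ## Deviation mechanisms differ by arm (initiators discontinue or switch;
  ## non-initiators start treatment), so the interval models are fitted
  ## separately per arm: numerator on the interval terms, denominator
  ## additionally on the covariates.
  ratio <- rep(1, nrow(long))
  covs <- intersect(covariates, names(long))
  keep <- covs[vapply(covs, function(cv) length(unique(long[[cv]])) > 1L,
                      logical(1))]
  x_cov <- if (length(keep)) {
    mm <- stats::model.matrix(
      ~ ., data = as.data.frame(lapply(long[keep], function(x)
        if (is.character(x)) factor(x) else x)))
    mm[, -1L, drop = FALSE]
  } else NULL
  for (arm in unique(long$initiator)) {
    g <- which(long$initiator == arm)
    y <- long$deviate[g]
    if (sum(y) == 0L) next            # no artificial censoring: weights 1
    kk <- (long$interval[g] - 12) / 6        # centred for conditioning
    x_num <- cbind(1, kk, kk^2)
    x_den <- if (is.null(x_cov)) x_num else {
      xc <- x_cov[g, , drop = FALSE]
      varying <- vapply(seq_len(ncol(xc)),
                        function(j) any(xc[, j] != xc[1L, j]), logical(1))
      cbind(x_num, xc[, varying, drop = FALSE])
    }
    num <- fast_logit_fit(x_num, y)
    den <- fast_logit_fit(x_den, y,
                          start = c(num$beta,
                                    numeric(ncol(x_den) - ncol(x_num))))
    ratio[g] <- (1 - num$prob) / pmax(1 - den$prob, 1e-12)
  }
  ## cumulative product within each person-trial (rows are contiguous)
  lr <- log(ratio)
  cs <- cumsum(lr)
  first <- c(TRUE, idx[-1L] != idx[-length(idx)])
  offs <- rep.int(cs[first] - lr[first], L)
  long$sw_cens <- exp(cs - offs)
  if (!is.null(truncate)) {
    q <- stats::quantile(long$sw_cens, truncate)
    long$sw_cens <- pmin(pmax(long$sw_cens, q[1L]), q[2L])
  }
  long$weight <- long$sw * long$sw_cens
  long <- long[long$tstop > long$tstart, , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "outcome") <- outcome
  attr(long, "interval_days") <- interval_days
  long
}

#' Weight summary and covariate-balance diagnostics
#'
#' @param data a weighted person-trial table (from [fit_iptw()])
#' @param weight_col weight column name (default `"sw"`)
#' @param covariates covariates for the balance table
#' @return an object of class `mht_weight_diagnostics`: weight summary
#'   (mean, max, tail percentiles, effective sample size) and, per
#'   covariate level, unweighted and weighted standardized mean
#'   differences between the arms
#' @export
weight_diagnostics <- function(data, weight_col = "sw",
                               covariates = DEFAULT_COVARIATES) {
  w <- data[[weight_col]]
  stopifnot(!is.null(w), all(w > 0))
  a <- data$initiator
  smd <- function(x, wt) {
    m1 <- stats::weighted.mean(x[a], wt[a])
    m0 <- stats::weighted.mean(x[!a], wt[!a])
    s <- sqrt((stats::var(x[a]) + stats::var(x[!a])) / 2)
    if (s == 0) 0 else (m1 - m0) / s
  }
  rows <- list()
  for (cv in intersect(covariates, names(data))) {
    x <- data[[cv]]
    if (is.character(x) || is.factor(x)) {
      for (lev in sort(unique(as.character(x))))
        rows[[paste(cv, lev, sep = ":")]] <- c(
          unweighted = smd(as.numeric(x == lev), rep(1, length(w))),
          weighted = smd(as.numeric(x == lev), w))
    } else {
      rows[[cv]] <- c(unweighted = smd(as.numeric(x), rep(1, length(w))),
                      weighted = smd(as.numeric(x), w))
    }
  }
  balance <- do.call(rbind, rows)
  out <- list(
    n = length(w),
    mean = mean(w), max = max(w),
    percentiles = stats::quantile(w, c(0.01, 0.5, 0.95, 0.99)),
    ess = sum(w)^2 / sum(w^2),
    mean_flag = abs(mean(w) - 1) > 0.05,
    balance = balance)
  class(out) <- "mht_weight_diagnostics"
  out
}

#' @export
print.mht_weight_diagnostics <- function(x, ...) {
  cat("Stabilized weight diagnostics\n")
  cat(sprintf("  n = %d, mean = %.4f%s, max = %.2f, ESS = %.0f\n",
              x$n, x$mean, if (x$mean_flag) " [FLAG: |mean-1| > 0.05]" else "",
              x$max, x$ess))
  cat(sprintf("  percentiles: 1%% %.3f, 50%% %.3f, 95%% %.3f, 99%% %.3f\n",
              x$percentiles[1L], x$percentiles[2L], x$percentiles[3L],
              x$percentiles[4L]))
  if (!is.null(x$balance)) {
    cat("  covariate balance (standardized differences):\n")
    print(round(x$balance, 4))
  }
  invisible(x)
}
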