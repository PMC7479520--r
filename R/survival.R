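# Survival analysis of CN-specific frequencies: single-covariate Cox models
# on log (pseudocounted) frequencies, Kaplan-Meier curves at the optimal
# split of the covariate, and proportional-hazards diagnostics via scaled
# Schoenfeld residuals.

#' Cox model on a log CN-specific frequency
#'
#' Fits `Surv(time, event) ~ log(pseudocount + frequency)` and reports the
#' log hazard ratio, its standard error, and the likelihood-ratio-test p
#' value, plus plot-ready partial-residual data (covariate, linear-predictor
#' term, martingale residuals).
#'
#' @param clinical Clinical data frame (`patient_id`, `survival_time`, `event`).
#' @param frequency Numeric frequencies named by patient_id (`NA` treated as 0).
#' @param pseudocount Added before the log (default 1e-3).
#' @param covariate_name Label for reporting.
#' @return List of class `cn_survfit`: `coef` (log HR), `se`, `hr`, `lrt_p`,
#'   `n`, `n_events`, `fit` (the coxph fit), `partial` (data frame
#'   patient_id, x, term, martingale).
#' @export
cox_cn_frequency <- function(clinical, frequency, pseudocount = 1e-3,
                             covariate_name = "log_cn_frequency") {
  f <- frequency[clinical$patient_id]
  x <- log_pc(f, pseudocount)
  if (sum(clinical$event) < 2) stop("need at least 2 events")
  if (stats::var(x) == 0) stop("no variation in covariate")
  dat <- data.frame(time = clinical$survival_time,
                    event = clinical$event, x = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                         ties = "efron")
  s <- summary(fit)
  partial <- data.frame(patient_id = clinical$patient_id, x = x,
                        term = unname(stats::coef(fit)[1]) * (x - mean(x)),
                        martingale = unname(stats::residuals(fit,
                                                             type = "martingale")),
                        stringsAsFactors = FALSE)
  structure(list(covariate = covariate_name,
                 coef = unname(stats::coef(fit)[1]),
                 se = s$coefficients[1, "se(coef)"],
                 hr = unname(exp(stats::coef(fit)[1])),
                 lrt_p = unname(s$logtest["pvalue"]),
                 n = nrow(dat), n_events = sum(dat$event),
                 fit = fit, partial = partial),
            class = "cn_survfit")
}

#' Kaplan-Meier curves at the optimal covariate split
#'
#' Scans all midpoints between sorted unique covariate values (with at least
#' `min_group` patients on each side) and picks the split minimising the
#' log-rank p value. The selected p value is optimistic (selection is not
#' corrected), which is reported as an attribute.
#'
#' @param clinical Clinical data frame (`patient_id`, `survival_time`, `event`).
#' @param covariate Numeric values named by patient_id.
#' @param min_group Minimum group size per side (default 3).
#' @return List of class `cn_km_split`: `split`, `logrank_p`, `km`
#'   (data frame group/time/surv of the two product-limit curves), `fit`
#'   (the survfit object), `candidates` (split value and p per candidate).
#' @export
km_optimal_split <- function(clinical, covariate, min_group = 3L) {
  x <- covariate[clinical$patient_id]
  if (anyNA(x)) stop("covariate missing for some patients")
  if (sum(clinical$event) < 1) stop("no events; cannot compute log-rank")
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("no admissible split: constant covariate")
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  cand <- mids[vapply(mids, function(m)
    sum(x <= m) >= min_group && sum(x > m) >= min_group, logical(1))]
  if (!length(cand)) stop("no admissible split under min_group = ", min_group)
  dat <- data.frame(time = clinical$survival_time, event = clinical$event)
  pvals <- vapply(cand, function(m) {
    g <- factor(x > m)
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
    stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  }, numeric(1))
  best <- which.min(pvals)
  g <- factor(ifelse(x > cand[best], "high", "low"), levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = dat)
  sm <- summary(fit)
  km <- data.frame(group = sub("^g=", "", as.character(sm$strata)),
                   time = sm$time, surv = sm$surv,
                   stringsAsFactors = FALSE)
  structure(list(split = cand[best], logrank_p = pvals[best], km = km,
                 fit = fit,
                 candidates = data.frame(split = cand, p = pvals)),
            class = "cn_km_split")
}

#' Proportional-hazards diagnostic
#'
#' Tests the association between scaled Schoenfeld residuals and time via
#' `survival::cox.zph`; a non-significant p supports proportional hazards.
#'
#' @param fit A `coxph` fit or a `cn_survfit`.
#' @param transform Time transform passed to `cox.zph` (default `"km"`).
#' @return The p value for the covariate; `NA` with a warning for fewer
#'   than 3 events.
#' @export
ph_diagnostic <- function(fit, transform = "km") {
  if (inherits(fit, "cn_survfit")) fit <- fit$fit
  nev <- fit$nevent
  if (is.null(nev) || nev < 3) {
    warning("fewer than 3 events; PH diagnostic unavailable")
    return(NA_real_)
  }
  z <- tryCatch(survival::cox.zph(fit, transform = transform),
                error = function(e) NULL)
  if (is.null(z)) {
    warning("cox.zph failed")
    return(NA_real_)
  }
  unname(z$table[1, "p"])
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around `survival::survfit` for a single (ungrouped) sample,
#' returning the step function values.
#'
#' @param time,event Survival times and 0/1 event indicators.
#' @return Data frame `time`, `n_risk`, `n_event`, `surv` at event times.
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  sm <- summary(fit, censored = FALSE)
  data.frame(time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, surv = sm$surv)
}
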