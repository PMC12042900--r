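#' Cohort association layer
#'
#' Endpoint harmonization from dated registry events and the association
#' models used in biobank CHIP studies: covariate-adjusted logistic
#' regression for prevalent endpoints (odds ratios), Cox
#' proportional-hazards models for survival (hazard ratios) with
#' hematologic-malignancy censoring, Kaplan-Meier/log-rank comparisons,
#' and the group tests used for clinical characteristics tables. All
#' reported p-values are two-sided; confidence intervals are Wald at 95%.
#'
#' @name association
NULL

.years_between <- function(from, to) as.numeric(to - from) / 365.25

#' Harmonize registry events into endpoint status per participant
#'
#' For each participant and each endpoint in `code_map`, determines whether
#' the endpoint is *prevalent* (first mapped code dated on or before the
#' DNA sampling date; set `strict_prevalent = TRUE` to count a same-day
#' code as incident instead) or *incident* (first mapped code after
#' sampling), with the time from sampling to the first post-sampling event
#' in years.
#'
#' @param records data.frame with `sample_id` and `sampling_date` (Date).
#' @param events Long data.frame with `sample_id`, `code`, `date` (Date);
#'   an event with a missing date is rejected with a diagnostic.
#' @param code_map Named list: endpoint name -> character vector of codes.
#' @param strict_prevalent Logical; when `TRUE`, a code dated exactly on
#'   the sampling date counts as incident, not prevalent.
#' @return data.frame with one row per (sample_id, endpoint):
#'   `prevalent`, `incident`, `first_event_date`, `time_to_event` (years,
#'   `NA` when no post-sampling event).
#' @export
harmonize_endpoints <- function(records, events, code_map,
                                strict_prevalent = FALSE) {
  stopifnot(is.data.frame(records), is.data.frame(events), is.list(code_map))
  if (nrow(events) > 0L && anyNA(events$date)) {
    bad <- which(is.na(events$date))[1L]
    stop("event row ", bad, " (sample ", events$sample_id[bad],
         ", code ", events$code[bad], ") has no date", call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(code_map), function(ep) {
    codes <- code_map[[ep]]
    ev <- events[events$code %in% codes, , drop = FALSE]
    first <- if (nrow(ev)) {
      stats::aggregate(date ~ sample_id, data = ev, FUN = min)
    } else data.frame(sample_id = character(0), date = as.Date(character(0)))
    m <- match(records$sample_id, first$sample_id)
    fd <- first$date[m]
    samp <- records$sampling_date
    prevalent <- !is.na(fd) &
      (if (strict_prevalent) fd < samp else fd <= samp)
    incident <- !is.na(fd) & !prevalent
    data.frame(sample_id = records$sample_id, endpoint = ep,
               prevalent = prevalent, incident = incident,
               first_event_date = fd,
               time_to_event = ifelse(incident, .years_between(samp, fd),
                                      NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign RA serotype with seropositive dominance
#'
#' A participant is `"seropositive"` if any seropositive code exists
#' anywhere in their record, `"seronegative"` only if seronegative codes
#' exist and *no* seropositive code does, and `"none"` otherwise. This is
#' the registry convention: a seronegative label is provisional and is
#' overridden by any seropositive code at any time.
#'
#' @param records data.frame with `sample_id`.
#' @param events Long events data.frame (`sample_id`, `code`, `date`).
#' @param code_map Named list containing the two serotype code sets.
#' @param positive,negative Names of the seropositive / seronegative
#'   entries in `code_map`.
#' @return Character vector along `records$sample_id` with values
#'   `"seropositive"`, `"seronegative"`, `"none"`.
#' @export
assign_serotype <- function(records, events, code_map,
                            positive = "ra_seropositive",
                            negative = "ra_seronegative") {
  pos_ids <- unique(events$sample_id[events$code %in% code_map[[positive]]])
  neg_ids <- unique(events$sample_id[events$code %in% code_map[[negative]]])
  ifelse(records$sample_id %in% pos_ids, "seropositive",
         ifelse(records$sample_id %in% neg_ids, "seronegative", "none"))
}

.new_effect <- function(exposure, outcome, measure, estimate, ci_low, ci_high,
                        p, n, n_excluded, exclusions, model_spec,
                        flags = character(0)) {
  structure(list(exposure = exposure, outcome = outcome, measure = measure,
                 estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 p = p, n = n, n_excluded = n_excluded,
                 exclusions = exclusions, model_spec = model_spec,
                 flags = flags),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s ~ %s: %s = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d\n",
              x$outcome, x$exposure, x$measure, x$estimate, x$ci_low,
              x$ci_high, x$p, x$n))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Complete-case subset with an exclusion log. `exclude` is a logical
# vector of a-priori exclusions (e.g. prevalent hematologic malignancy).
.complete_case <- function(data, cols, exclude = NULL, exclude_reason = NULL) {
  log <- data.frame(sample_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(data))
  sid <- if ("sample_id" %in% names(data)) data$sample_id else
    as.character(seq_len(nrow(data)))
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == nrow(data))
    drop <- which(exclude & keep)
    if (length(drop)) {
      log <- rbind(log, data.frame(sample_id = sid[drop],
                                   reason = exclude_reason %||% "a-priori exclusion",
                                   stringsAsFactors = FALSE))
      keep[drop] <- FALSE
    }
  }
  for (col in cols) {
    drop <- which(keep & is.na(data[[col]]))
    if (length(drop)) {
      log <- rbind(log, data.frame(sample_id = sid[drop],
                                   reason = paste0("missing ", col),
                                   stringsAsFactors = FALSE))
      keep[drop] <- FALSE
    }
  }
  list(data = data[keep, , drop = FALSE], log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.wald_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(exp(beta - z * se), exp(beta + z * se))
}

#' Covariate-adjusted logistic model for a prevalent endpoint
#'
#' Maximum-likelihood logistic regression of a binary prevalent outcome on
#' a binary exposure plus covariates (canonically age, sex, smoking
#' history ever/never, and 10 ancestry principal components). Handling
#' follows the biobank convention: participants matching `exclude`
#' (typically prevalent hematologic malignancy) are removed first, then
#' complete-case filtering on exposure, outcome and covariates; every
#' dropped row is logged with a reason, and the reported `n` is the input
#' n minus logged exclusions. The odds ratio is `exp(coef)` with a Wald
#' 95% CI and a two-sided Wald p.
#'
#' Complete separation is flagged (enormous coefficient or standard error,
#' or non-convergence) on the returned object rather than raised.
#'
#' @param data One row per participant.
#' @param exposure,outcome Column names of 0/1 or logical variables.
#' @param covariates Character vector of adjustment column names.
#' @param exclude Optional logical vector: rows to drop before fitting.
#' @param exclude_reason Label recorded in the exclusion log.
#' @return An `"effect_estimate"` (measure `"OR"`) carrying the exclusion
#'   log and model specification.
#' @export
prevalent_logistic <- function(data, exposure, outcome,
                               covariates = character(0),
                               exclude = NULL,
                               exclude_reason = "prevalent hematologic malignancy") {
  cc <- .complete_case(data, c(exposure, outcome, covariates),
                       exclude, exclude_reason)
  d <- cc$data
  if (nrow(d) == 0L) stop("no rows left after exclusions", call. = FALSE)
  fm <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::glm(fm, family = stats::binomial(), data = d)
  co <- summary(fit)$coefficients
  row <- grep(paste0("^", exposure), rownames(co))[1L]
  beta <- co[row, 1]; se <- co[row, 2]; p <- co[row, 4]
  ci <- .wald_ci(beta, se)
  flags <- character(0)
  if (!fit$converged) flags <- c(flags, "glm did not converge")
  if (abs(beta) > 10 || se > 50) flags <- c(flags, "possible complete separation")
  .new_effect(exposure, outcome, "OR", exp(beta), ci[1], ci[2], p,
              n = nrow(d), n_excluded = nrow(cc$log), exclusions = cc$log,
              model_spec = list(formula = deparse(fm), covariates = covariates,
                                exclude_reason = if (is.null(exclude)) NULL else exclude_reason),
              flags = flags)
}

#' Build survival time and status with hematologic-malignancy censoring
#'
#' Time origin is the DNA sampling date. Follow-up ends at the earliest of
#' the death date, the administrative censoring date, and (when supplied)
#' the date of an incident hematologic malignancy; the participant is an
#' event (status 1) only if death is that earliest date. An incident
#' malignancy occurring before death therefore converts the death into a
#' censoring.
#'
#' @param records data.frame with `sampling_date`, `censor_date` (Date)
#'   and `death_date` (Date, `NA` when alive).
#' @param hem_date Optional Date vector along rows: first incident
#'   hematologic-malignancy date (`NA` when none).
#' @return data.frame with `time` (years, non-negative) and `status`
#'   (1 death, 0 censored).
#' @export
build_survival <- function(records, hem_date = NULL) {
  end <- records$censor_date
  if (!is.null(hem_date)) {
    stopifnot(length(hem_date) == nrow(records))
    end <- pmin(end, hem_date, na.rm = TRUE)  # pmin preserves the Date class
  }
  death <- records$death_date
  is_event <- !is.na(death) & death <= end
  stop_date <- end
  stop_date[is_event] <- death[is_event]
  data.frame(time = pmax(.years_between(records$sampling_date, stop_date), 0),
             status = as.integer(is_event))
}

#' Cox proportional-hazards association model
#'
#' Fits `survival::coxph` of (`time`, `status`) on a binary exposure plus
#' covariates, reporting the exposure hazard ratio with a Wald 95% CI and
#' a two-sided p. Complete-case exclusions are logged as in
#' [prevalent_logistic()]. Strata with no events are flagged.
#'
#' @param data One row per participant with `time` and `status` columns
#'   (see [build_survival()]).
#' @param exposure,covariates As in [prevalent_logistic()].
#' @param exclude,exclude_reason Optional a-priori exclusions.
#' @return An `"effect_estimate"` (measure `"HR"`).
#' @export
survival_cox <- function(data, exposure, covariates = character(0),
                         exclude = NULL, exclude_reason = "excluded") {
  cc <- .complete_case(data, c("time", "status", exposure, covariates),
                       exclude, exclude_reason)
  d <- cc$data
  if (nrow(d) == 0L) stop("no rows left after exclusions", call. = FALSE)
  flags <- character(0)
  for (lev in unique(d[[exposure]])) {
    if (sum(d$status[d[[exposure]] == lev]) == 0L) {
      flags <- c(flags, paste0("no events in stratum ", exposure, "=", lev))
    }
  }
  fm <- stats::reformulate(c(exposure, covariates),
                           response = "survival::Surv(time, status)")
  fit <- survival::coxph(fm, data = d)
  co <- summary(fit)$coefficients
  row <- grep(paste0("^", exposure), rownames(co))[1L]
  beta <- co[row, "coef"]; se <- co[row, "se(coef)"]
  p <- co[row, "Pr(>|z|)"]
  ci <- .wald_ci(beta, se)
  if (abs(beta) > 10 || se > 50) flags <- c(flags, "unstable estimate")
  .new_effect(exposure, "survival", "HR", exp(beta), ci[1], ci[2], p,
              n = nrow(d), n_excluded = nrow(cc$log), exclusions = cc$log,
              model_spec = list(formula = deparse(fm), covariates = covariates),
              flags = flags)
}

#' Kaplan-Meier curves with a log-rank (Mantel-Cox) test
#'
#' Kaplan-Meier estimates per group, the two-sided log-rank p for group
#' differences (absent with a single group), and the survival probability
#' per group at an optional horizon.
#'
#' @param time,status Survival outcome (years; 1 = event).
#' @param group Grouping vector (single group allowed).
#' @param horizon Optional time at which to read off survival.
#' @return List of class `"km_result"`: `fit` (a `survfit` object),
#'   `logrank_p` (`NA` for one group), `horizon_survival` (named numeric,
#'   when requested).
#' @export
km_logrank <- function(time, status, group = rep("all", length(time)),
                       horizon = NULL) {
  d <- data.frame(time = time, status = status, group = as.character(group),
                  stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = d)
  p <- NA_real_
  if (length(unique(d$group)) > 1L) {
    sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = d)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  }
  hs <- NULL
  if (!is.null(horizon)) {
    sm <- summary(fit, times = horizon, extend = TRUE)
    grp <- if (is.null(sm$strata)) "all" else sub("^group=", "", as.character(sm$strata))
    hs <- stats::setNames(sm$surv, grp)
  }
  structure(list(fit = fit, logrank_p = p, horizon_survival = hs),
            class = "km_result")
}

#' Group tests for clinical characteristics
#'
#' The tests used in cohort characteristics tables: Kruskal-Wallis for a
#' continuous variable across k groups, Fisher's exact test (two-sided)
#' for a 2x2 table, and Pearson's chi-squared (without continuity
#' correction) for larger tables or as an alternative 2x2 test.
#'
#' @param values Numeric vector (Kruskal-Wallis).
#' @param groups Grouping vector parallel to `values`.
#' @param table A contingency table/matrix (Fisher or chi-squared).
#' @param method `"kruskal"`, `"fisher"`, or `"chisq"`.
#' @return The two-sided p-value.
#' @export
group_test <- function(values = NULL, groups = NULL, table = NULL,
                       method = c("kruskal", "fisher", "chisq")) {
  method <- match.arg(method)
  switch(method,
    kruskal = {
      stopifnot(!is.null(values), !is.null(groups))
      stats::kruskal.test(values, as.factor(groups))$p.value
    },
    fisher = {
      stopifnot(!is.null(table))
      stats::fisher.test(table)$p.value
    },
    chisq = {
      stopifnot(!is.null(table))
      stats::chisq.test(table, correct = FALSE)$p.value
    }
  )
}

#' Area under the DAS28 curve over a follow-up horizon
#'
#' Trapezoidal integral of serial 28-joint disease activity scores from
#' diagnosis (month 0) to `horizon` months, in score-months. A series
#' extending past the horizon is linearly interpolated at the horizon and
#' truncated; a series ending before the horizon is integrated to its last
#' visit. At least two points are required and the first must be at
#' month 0.
#'
#' @param months Visit times in months since diagnosis, sorted ascending.
#' @param das28 DAS28 scores at those visits.
#' @param horizon Integration horizon in months (default 24).
#' @return The AUC in score-months.
#' @export
das28_auc <- function(months, das28, horizon = 24) {
  stopifnot(length(months) == length(das28))
  if (length(months) < 2L) stop("need at least two visits", call. = FALSE)
  if (is.unsorted(months, strictly = TRUE)) {
    stop("visit times must be strictly increasing", call. = FALSE)
  }
  if (months[1L] != 0) stop("first visit must be at month 0", call. = FALSE)
  if (months[length(months)] > horizon) {
    y_h <- stats::approx(months, das28, xout = horizon)$y
    keep <- months < horizon
    months <- c(months[keep], horizon)
    das28 <- c(das28[keep], y_h)
  }
  sum(diff(months) * (utils::head(das28, -1L) + utils::tail(das28, -1L)) / 2)
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Carrier prevalence by age bin with Wilson 95% CIs
#'
#' @param carrier Logical carrier status per participant.
#' @param age Age at sampling, years.
#' @param breaks Bin edges (default decades 20-100); bins partition the
#'   cohort, so bin counts sum to the input n.
#' @return data.frame: `bin`, `n`, `n_carriers`, `prevalence`, `ci_low`,
#'   `ci_high`.
#' @export
prevalence_by_age <- function(carrier, age, breaks = seq(20, 100, by = 10)) {
  stopifnot(length(carrier) == length(age))
  bins <- cut(age, breaks = breaks, include.lowest = TRUE, right = FALSE)
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    idx <- which(bins == b)
    x <- sum(carrier[idx]); n <- length(idx)
    ci <- wilson_ci(x, n)
    data.frame(bin = b, n = n, n_carriers = x,
               prevalence = if (n > 0) x / n else NA_real_,
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Format a count ratio the way results tables print it
#'
#' `percentage(121, 10021)` is `"1.2%"`; the numeric value is also
#' available via `ratio_percent()`.
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places (default 1).
#' @return `percentage()`: a string like `"18.1%"`; `ratio_percent()`: the
#'   rounded numeric percentage.
#' @export
percentage <- function(num, den, digits = 1) {
  paste0(formatC(ratio_percent(num, den, digits), format = "f",
                 digits = digits), "%")
}

#' @rdname percentage
#' @export
ratio_percent <- function(num, den, digits = 1) {
  if (den <= 0) stop("denominator must be positive", call. = FALSE)
  round(100 * num / den, digits)
}
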