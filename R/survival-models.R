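# Survival statistics: Cox regression, Harrell c-index (plain,
# cross-validated and bootstrap-compared), Kaplan-Meier estimation with a
# median split, the rank-sum group test and the recurrence-pattern rule.

#' Fit a Cox proportional hazards model
#'
#' Maximum partial likelihood with Efron tie handling. Reports per-covariate
#' hazard ratios with Wald 95% CIs and p-values, plus the model's Harrell
#' c-index on its own linear predictor. Monotone-likelihood pathologies
#' (coefficients diverging, yielding absurd hazard-ratio magnitudes) are
#' flagged rather than silently reported.
#'
#' @param data Cohort data frame with time/event columns and covariates.
#' @param covariates Character vector of covariate column names.
#' @param time_col,event_col Column names (defaults `time_months`, `event`).
#' @return A `cox_fit`: coefficient table, c-index, n, n_events, flags.
#' @export
cox_fit <- function(data, covariates, time_col = "time_months",
                    event_col = "event") {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  if (sum(data[[event_col]]) < 2) {
    stop("need at least 2 events to fit a Cox model", call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")
  ))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  tab <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hr = co[, "exp(coef)"],
    hr_lower = ci[, "lower .95"],
    hr_upper = ci[, "upper .95"],
    p_value = co[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(abs(tab$coef) > 15)) {
    flags <- c(flags, "possible monotone likelihood: |coef| > 15, hazard ratios unreliable")
  }
  lp <- as.numeric(stats::predict(fit, type = "lp"))
  structure(
    list(
      table = tab, model = fit,
      cindex = c_index(lp, data[[time_col]], data[[event_col]]),
      n = s$n, n_events = s$nevent, flags = flags,
      covariates = covariates, time_col = time_col, event_col = event_col
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, c-index = %.3f\n",
              x$n, x$n_events, x$cindex))
  print(transform(x$table, coef = round(coef, 4), hr = signif(hr, 4),
                  hr_lower = signif(hr_lower, 4), hr_upper = signif(hr_upper, 4),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Harrell concordance index
#'
#' A pair of subjects is comparable iff the shorter observed time ends in an
#' event; a comparable pair is concordant when the subject with the shorter
#' time has the higher risk score, and tied risk scores count 1/2. The
#' c-index is (concordant + 0.5 * tied) / comparable: 0.5 is random
#' discrimination, 1 is perfect.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param time,event Survival outcome.
#' @return The c-index in `[0, 1]`.
#' @export
c_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  earlier <- outer(time, time, "<")     # [i, j]: t_i < t_j
  comparable <- earlier & (event == 1)  # event recycles over rows = event_i
  den <- sum(comparable)
  if (den == 0) stop("no comparable pairs", call. = FALSE)
  higher <- outer(risk, risk, ">")
  tied <- outer(risk, risk, "==")
  (sum(higher & comparable) + 0.5 * sum(tied & comparable)) / den
}

# Random fold assignment with every training fold guaranteed >= 2 events;
# falls back to event-stratified assignment when a plain draw fails.
assign_folds <- function(event, k) {
  n <- length(event)
  folds <- sample(rep_len(seq_len(k), n))
  ok <- all(vapply(seq_len(k), function(f) sum(event[folds != f]) >= 2,
                   logical(1)))
  if (!ok) {
    message("refolding with event stratification")
    folds <- integer(n)
    for (grp in unique(event)) {
      i <- which(event == grp)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  }
  folds
}

#' Cross-validated Harrell c-index of a Cox model
#'
#' K-fold cross-validation: the model is fitted on k-1 folds, the linear
#' predictor is scored on the held-out fold, and the c-index is computed on
#' the pooled held-out predictions. Fold assignment is seeded and
#' event-stratified when a plain random assignment leaves a training fold
#' without events.
#'
#' @inheritParams cox_fit
#' @param k Number of folds (default 10).
#' @param seed Integer seed or NULL.
#' @return A list: `cindex`, `risk` (pooled held-out linear predictor),
#'   `folds`.
#' @export
crossvalidated_cindex <- function(data, covariates, k = 10, seed = NULL,
                                  time_col = "time_months",
                                  event_col = "event") {
  n <- nrow(data)
  stopifnot(n >= k)
  maybe_set_seed(seed)
  folds <- assign_folds(data[[event_col]], k)
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")
  ))
  risk <- numeric(n)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    fit <- survival::coxph(fml, data = train, ties = "efron")
    risk[folds == f] <- as.numeric(
      stats::predict(fit, newdata = data[folds == f, , drop = FALSE],
                     type = "lp")
    )
  }
  list(
    cindex = c_index(risk, data[[time_col]], data[[event_col]]),
    risk = risk, folds = folds
  )
}

#' Compare two risk models by paired bootstrap of the c-index difference
#'
#' Both risk score vectors are evaluated on the same subjects; subjects are
#' resampled with replacement and the difference `delta = c_a - c_b` is
#' recomputed on each resample, giving a percentile CI and a two-sided
#' bootstrap p-value. Degenerate resamples (no comparable pairs) are redrawn
#' and counted. Identical models give delta = 0 exactly and p = 1.
#'
#' @param risk_a,risk_b Risk scores of the two models (same subjects).
#' @param time,event Survival outcome.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed or NULL.
#' @return A list: `delta`, `ci` (2.5/97.5 percentiles), `p_value`,
#'   `cindex_a`, `cindex_b`, `n_redraws`.
#' @export
compare_cindex <- function(risk_a, risk_b, time, event, n_boot = 2000,
                           seed = NULL) {
  n <- length(time)
  stopifnot(length(risk_a) == n, length(risk_b) == n, length(event) == n)
  maybe_set_seed(seed)
  ca <- c_index(risk_a, time, event)
  cb <- c_index(risk_b, time, event)
  delta <- ca - cb
  if (identical(risk_a, risk_b)) {
    return(list(delta = 0, ci = c(0, 0), p_value = 1,
                cindex_a = ca, cindex_b = cb, n_redraws = 0L))
  }
  deltas <- numeric(n_boot)
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      d <- tryCatch(
        c_index(risk_a[idx], time[idx], event[idx]) -
          c_index(risk_b[idx], time[idx], event[idx]),
        error = function(e) NULL
      )
      if (!is.null(d)) break
      n_redraws <- n_redraws + 1L
    }
    deltas[b] <- d
  }
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(
    delta = delta,
    ci = unname(stats::quantile(deltas, c(0.025, 0.975))),
    p_value = min(1, p),
    cindex_a = ca, cindex_b = cb, n_redraws = n_redraws
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event Survival outcome.
#' @return A `km_estimate`: event/censoring times, survival probabilities,
#'   at-risk counts and Greenwood CIs (from [survival::survfit()]).
#' @export
km_estimate <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(
    list(
      time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
      n_event = sf$n.event, lower = sf$lower, upper = sf$upper,
      n = length(time)
    ),
    class = "km_estimate"
  )
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step evaluation; times before the first observed time
#' return 1.
#'
#' @param km A [km_estimate()].
#' @param t Numeric vector of evaluation times.
#' @return Survival probabilities.
#' @export
km_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  stats::stepfun(km$time, c(1, km$surv), right = FALSE)(t)
}

#' Median-split Kaplan-Meier curves with a log-rank test
#'
#' Splits the cohort at the median of a feature (ties go to the low group),
#' estimates a KM curve per group and computes the two-sample log-rank
#' statistic.
#'
#' @param data Cohort data frame.
#' @param feature Feature column name (non-constant).
#' @param time_col,event_col Outcome column names.
#' @return A list: `low`, `high` ([km_estimate()]s), `logrank_chisq`,
#'   `p_value`, `median`, `n_low`, `n_high`.
#' @export
km_median_split <- function(data, feature, time_col = "time_months",
                            event_col = "event") {
  v <- data[[feature]]
  if (is.null(v)) stop("unknown feature: ", feature, call. = FALSE)
  if (stats::sd(v) == 0) stop("feature is constant", call. = FALSE)
  med <- stats::median(v)
  grp <- factor(ifelse(v <= med, "low", "high"), levels = c("low", "high"))
  if (min(table(grp)) < 2) {
    warning("a median-split group has fewer than 2 subjects")
  }
  sd_ <- survival::survdiff(
    stats::as.formula(paste0("survival::Surv(", time_col, ", ", event_col,
                             ") ~ grp")),
    data = cbind(data, grp = grp)
  )
  chisq <- sd_$chisq
  list(
    low = km_estimate(data[[time_col]][grp == "low"],
                      data[[event_col]][grp == "low"]),
    high = km_estimate(data[[time_col]][grp == "high"],
                       data[[event_col]][grp == "high"]),
    logrank_chisq = chisq,
    p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    median = med,
    n_low = sum(grp == "low"), n_high = sum(grp == "high")
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact distribution when both groups have at most 20 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Identical constant groups return p = 1.
#'
#' @param x,y Numeric samples for the two groups.
#' @return A list: `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  all_vals <- c(x, y)
  if (length(unique(all_vals)) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all values identical)"))
  }
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !any(duplicated(all_vals))
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Classify a recurrence pattern from isodose coverage
#'
#' Fraction of the recurrence volume inside the prescription 95% isodose
#' surface: above 0.80 is "in-field", between 0.20 and 0.80 (inclusive) is
#' "marginal", below 0.20 is "out-field".
#'
#' @param fraction_inside Numeric vector of fractions in `[0, 1]`.
#' @return Character vector of labels.
#' @export
classify_recurrence_pattern <- function(fraction_inside) {
  if (any(is.na(fraction_inside)) ||
      any(fraction_inside < 0 | fraction_inside > 1)) {
    stop("`fraction_inside` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(fraction_inside > 0.80, "in-field",
         ifelse(fraction_inside >= 0.20, "marginal", "out-field"))
}
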