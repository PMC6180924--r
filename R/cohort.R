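# Synthetic survival cohorts with an exponential proportional-hazards link to
# image features, plus clinical covariates mirroring a typical head-and-neck
# chemoradiotherapy population (predominantly male, stage IV, oropharynx).

#' Specify a synthetic survival cohort
#'
#' @param n_subjects Positive integer.
#' @param censoring_rate Target fraction of censored subjects, in `[0, 1)`.
#'   Independent uniform censoring is calibrated so the expected censored
#'   fraction matches this value.
#' @param baseline_hazard Baseline event rate per month (default 0.02,
#'   i.e. a median time to event of about 35 months at null covariates).
#' @param log_hr_per_feature Named list/vector: log hazard ratio per 1-SD
#'   increase of each named image feature.
#' @param seed Integer seed or NULL.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, censoring_rate = 0.3,
                        baseline_hazard = 0.02,
                        log_hr_per_feature = list(), seed = NULL) {
  stopifnot(
    n_subjects >= 1, censoring_rate >= 0, censoring_rate < 1,
    baseline_hazard > 0
  )
  log_hr_per_feature <- unlist(log_hr_per_feature)
  if (length(log_hr_per_feature) &&
      is.null(names(log_hr_per_feature))) {
    stop("`log_hr_per_feature` must be named by feature", call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), censoring_rate = censoring_rate,
      baseline_hazard = baseline_hazard,
      log_hr_per_feature = log_hr_per_feature, seed = seed
    ),
    class = "cohort_spec"
  )
}

# Draw the fixed clinical covariate scheme: gender Bernoulli(0.75 male), age
# uniform 40-80 y, stage Bernoulli(0.65 IV), site Bernoulli(0.55 oropharynx),
# concurrent chemotherapy Bernoulli(0.7 yes); weight/height by sex for the
# lean-body-mass scaling of SUL.
draw_covariates <- function(n) {
  gender <- ifelse(stats::runif(n) < 0.75, "M", "F")
  male <- gender == "M"
  data.frame(
    gender = factor(gender, levels = c("F", "M")),
    age = round(stats::runif(n, 40, 80), 1),
    stage = factor(ifelse(stats::runif(n) < 0.65, "IV", "III"),
                   levels = c("III", "IV")),
    site_group = factor(ifelse(stats::runif(n) < 0.55, "oropharynx", "other"),
                        levels = c("oropharynx", "other")),
    cht = factor(ifelse(stats::runif(n) < 0.7, "yes", "no"),
                 levels = c("no", "yes")),
    weight_kg = round(ifelse(male, stats::rnorm(n, 78, 12),
                             stats::rnorm(n, 64, 10)), 1),
    height_cm = round(ifelse(male, stats::rnorm(n, 175, 7),
                             stats::rnorm(n, 162, 6)), 1),
    stringsAsFactors = FALSE
  )
}

# Solve for the upper bound u of U(0, u) censoring such that the expected
# censored fraction over the drawn event times equals `rate`.
calibrate_censoring_bound <- function(event_times, rate) {
  f <- function(u) mean(pmin(event_times / u, 1)) - rate
  lo <- min(event_times) * 1e-4
  hi <- max(event_times) / max(rate, 1e-12)
  while (f(hi) > 0) hi <- hi * 10
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Generate a synthetic survival cohort from a feature table
#'
#' Event times follow an exponential proportional-hazards model with linear
#' predictor `sum(beta_f * standardized feature)`; censoring is independent
#' uniform, calibrated to the target censoring rate in expectation.
#'
#' @param spec A [cohort_spec()]; `spec$n_subjects` must equal `nrow(features)`.
#' @param features Data frame of per-subject feature values containing every
#'   feature named in `spec$log_hr_per_feature` (an optional `subject_id`
#'   column is carried through).
#' @return A data frame with `subject_id`, `time_months`, `event`, the
#'   clinical covariates and all feature columns.
#' @export
generate_cohort <- function(spec, features) {
  stopifnot(inherits(spec, "cohort_spec"), is.data.frame(features))
  n <- spec$n_subjects
  if (nrow(features) != n) {
    stop(sprintf("`features` has %d rows but the spec asks for %d subjects",
                 nrow(features), n), call. = FALSE)
  }
  beta <- spec$log_hr_per_feature
  missing_f <- setdiff(names(beta), names(features))
  if (length(missing_f)) {
    stop("features missing from the table: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  maybe_set_seed(spec$seed)
  covars <- draw_covariates(n)
  lp <- rep(0, n)
  for (f in names(beta)) {
    v <- features[[f]]
    s <- stats::sd(v)
    z <- if (is.na(s) || s == 0) rep(0, n) else (v - mean(v)) / s
    lp <- lp + beta[[f]] * z
  }
  t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(lp))
  if (spec$censoring_rate > 0) {
    u <- calibrate_censoring_bound(t_event, spec$censoring_rate)
    t_cens <- stats::runif(n, 0, u)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  subject_id <- features$subject_id %||% sprintf("S%03d", seq_len(n))
  feat_cols <- features[setdiff(names(features), "subject_id")]
  cbind(
    data.frame(subject_id = subject_id, time_months = time, event = event,
               stringsAsFactors = FALSE),
    covars, feat_cols
  )
}

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("gender", "stage", "site_group", "cht")) {
    if (col %in% names(x)) x[[col]] <- factor(x[[col]])
  }
  x
}
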