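# Repeated-LASSO stability selection for penalized Cox models, plus the
# Spearman/Pearson correlation screens used to check redundancy between
# selected features and independence from clinical covariates.

#' Fit an L1-penalized Cox model at a given penalty
#'
#' Maximizes the L1-penalized Cox partial likelihood (coordinate descent via
#' glmnet); coefficients outside the active set are exactly zero. Penalties
#' at or above the path maximum give the empty model; `lambda = 0` recovers
#' the unpenalized Cox fit. Constant columns are dropped with a warning
#' (reported as zero coefficients).
#'
#' @param x Numeric feature matrix (columns should be standardized; no
#'   standardization is applied here).
#' @param time,event Survival outcome (time > 0, event 0/1).
#' @param lambda Single penalty value >= 0.
#' @return Named coefficient vector over the columns of `x`.
#' @export
fit_lasso_cox <- function(x, time, event, lambda) {
  stopifnot(is.matrix(x), length(time) == nrow(x), length(event) == nrow(x),
            length(lambda) == 1, lambda >= 0)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping constant columns: ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  beta <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (!any(keep)) return(beta)
  xs <- x[, keep, drop = FALSE]
  y <- survival::Surv(time, event)
  # run coordinate descent down a warm-start path ending at the requested
  # penalty; a cold single-lambda fit is unreliable
  path <- glmnet::glmnet(xs, y, family = "cox", standardize = FALSE)
  lams <- path$lambda[path$lambda > lambda]
  fit <- glmnet::glmnet(xs, y, family = "cox", standardize = FALSE,
                        lambda = c(lams, lambda), thresh = 1e-12)
  beta[colnames(xs)] <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  beta
}

#' Stability selection by repeated cross-validated LASSO
#'
#' Each run draws a bootstrap resample of subjects (or uses the full cohort
#' when `resample = "none"`), standardizes the columns within the resample,
#' picks the penalty minimizing the 10-fold cross-validated partial-likelihood
#' deviance on a log-spaced grid, and records the active set. Features
#' selected in strictly more than `threshold` of the runs form the selected
#' set. Resamples that are degenerate (e.g. all censored) are redrawn and
#' counted.
#'
#' @param x Numeric feature matrix with column names.
#' @param time,event Survival outcome.
#' @param n_runs Number of repetitions (default 1000).
#' @param threshold Selection frequency threshold, strict (default 0.5,
#'   i.e. "more than 500 of 1000 runs").
#' @param seed Integer seed or NULL.
#' @param resample `"bootstrap"` (default) or `"none"` (randomness from the
#'   cross-validation folds only).
#' @param nfolds Cross-validation folds per run (default 10).
#' @param nlambda Penalty grid size (default 50).
#' @param lambda_rule Per-run penalty choice: `"1se"` (default; the largest
#'   penalty within one standard error of the minimum cross-validated
#'   deviance, the parsimonious standard rule, which keeps the selection
#'   frequency of independent noise features well below the threshold) or
#'   `"min"` (the deviance-minimizing penalty, which is known to overselect
#'   noise features).
#' @return A `stability_result`: counts, frequencies, selected set, settings.
#' @export
stability_select <- function(x, time, event, n_runs = 1000, threshold = 0.5,
                             seed = NULL, resample = c("bootstrap", "none"),
                             nfolds = 10, nlambda = 50,
                             lambda_rule = c("1se", "min")) {
  resample <- match.arg(resample)
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(x), !is.null(colnames(x)), n_runs >= 1)
  maybe_set_seed(seed)
  n <- nrow(x)
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  n_redraws <- 0L
  for (run in seq_len(n_runs)) {
    repeat {
      idx <- if (resample == "bootstrap") {
        sample.int(n, n, replace = TRUE)
      } else {
        seq_len(n)
      }
      if (sum(event[idx]) >= max(2, nfolds / 2)) {
        active <- tryCatch({
          xs <- x[idx, , drop = FALSE]
          mu <- colMeans(xs)
          sds <- apply(xs, 2, stats::sd)
          ok <- sds > 0
          xs <- scale(xs[, ok, drop = FALSE], center = mu[ok], scale = sds[ok])
          cv <- glmnet::cv.glmnet(
            xs, survival::Surv(time[idx], event[idx]),
            family = "cox", standardize = FALSE,
            nfolds = nfolds, nlambda = nlambda
          )
          b <- as.numeric(stats::coef(
            cv, s = if (lambda_rule == "1se") "lambda.1se" else "lambda.min"
          ))
          colnames(xs)[b != 0]
        }, error = function(e) NULL)
        if (!is.null(active)) break
      }
      n_redraws <- n_redraws + 1L
      if (resample == "none") {
        stop("cross-validated fit failed on the full cohort", call. = FALSE)
      }
    }
    counts[active] <- counts[active] + 1L
  }
  freq <- counts / n_runs
  structure(
    list(
      n_runs = n_runs, counts = counts, frequency = freq,
      selected = names(freq)[freq > threshold], threshold = threshold,
      resample = resample, nfolds = nfolds, nlambda = nlambda,
      lambda_rule = lambda_rule,
      n_redraws = n_redraws, seed = seed
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d runs (%s resampling), threshold > %.2f\n",
              x$n_runs, x$resample, x$threshold))
  ord <- order(-x$frequency)
  print(round(x$frequency[ord], 3))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Correlation between two numeric vectors
#'
#' Spearman (average ranks for ties) or Pearson correlation; constant input
#' yields NA with a warning.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation in `[-1, 1]`, or NA.
#' @export
correlation_screen <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Flag correlated feature pairs and feature-clinical pairs
#'
#' Selected-feature pairs with `|Spearman rho| >= rho_feature` and
#' feature-clinical pairs with `|Pearson rho| >= rho_clinical` are flagged as
#' redundant / non-independent.
#'
#' @param features Data frame of selected feature columns.
#' @param clinical Optional data frame of numeric clinical covariates.
#' @param rho_feature Spearman flag threshold (default 0.6).
#' @param rho_clinical Pearson flag threshold (default 0.2).
#' @return Data frame of all screened pairs with rho, method and flag.
#' @export
correlation_report <- function(features, clinical = NULL,
                               rho_feature = 0.6, rho_clinical = 0.2) {
  rows <- list()
  fn <- names(features)
  if (length(fn) >= 2) {
    for (i in seq_len(length(fn) - 1)) {
      for (j in (i + 1):length(fn)) {
        rho <- suppressWarnings(
          correlation_screen(features[[i]], features[[j]], "spearman")
        )
        rows[[length(rows) + 1]] <- data.frame(
          a = fn[i], b = fn[j], method = "spearman", rho = rho,
          flagged = !is.na(rho) && abs(rho) >= rho_feature,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!is.null(clinical)) {
    for (f in fn) {
      for (cl in names(clinical)) {
        v <- clinical[[cl]]
        if (is.factor(v)) v <- as.numeric(v)
        rho <- suppressWarnings(
          correlation_screen(features[[f]], v, "pearson")
        )
        rows[[length(rows) + 1]] <- data.frame(
          a = f, b = cl, method = "pearson", rho = rho,
          flagged = !is.na(rho) && abs(rho) >= rho_clinical,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(a = character(), b = character(), method = character(),
                      rho = numeric(), flagged = logical()))
  }
  do.call(rbind, rows)
}
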