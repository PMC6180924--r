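test_that("Cox regression recovers a known log rate ratio", {
  set.seed(1)
  n <- 2000
  grp <- rep(0:1, each = n / 2)
  d <- data.frame(
    time_months = rexp(n, rate = 0.05 * 2^grp),
    event = 1L, grp = grp
  )
  fit <- cox_fit(d, "grp")
  expect_lt(abs(fit$table$coef - log(2)), 0.1)
  expect_gt(fit$cindex, 0.5)
})

test_that("a covariate independent of outcome has HR near 1", {
  set.seed(2)
  d <- data.frame(time_months = rexp(500, 0.05), event = 1L, x = rnorm(500))
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$table$hr - 1), 0.2)
})

test_that("the partial likelihood matches a hand-built two-event oracle", {
  # events at t=1 (x=1) and t=2 (x=0), censored follow-up in both arms:
  # PL(b) = [e^b / (2 e^b + 2)] * [1 / (e^b + 2)]
  d <- data.frame(time_months = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 0L),
                  x = c(1, 0, 1, 0))
  neg_log_pl <- function(b) {
    -(b - log(2 * exp(b) + 2) - log(exp(b) + 2))
  }
  oracle <- optimize(neg_log_pl, c(-5, 5))$minimum
  fit <- cox_fit(d, "x")
  expect_lt(abs(fit$table$coef - oracle), 1e-4)
})

test_that("diverging coefficients raise a monotone-likelihood flag", {
  d <- data.frame(time_months = c(1, 2, 3, 10, 11, 12),
                  event = c(1L, 1L, 1L, 1L, 1L, 1L),
                  x = c(1, 1, 1, 0, 0, 0))  # perfect separation in time
  fit <- cox_fit(d, "x")
  expect_true(length(fit$flags) > 0)
})

test_that("the c-index hits its documented endpoints and hand value", {
  # perfectly rank-ordered risk, no censoring
  expect_equal(c_index(-(1:100), 1:100, rep(1, 100)), 1.0)
  # hand enumeration: 3 comparable pairs, 2 concordant
  expect_equal(c_index(c(3, 1, 2), c(1, 2, 3), c(1, 1, 1)), 2 / 3)
  # outcome-independent risk
  d <- sim_survival(800, beta = 0, censor_frac = 0.2, seed = 4)
  expect_lt(abs(c_index(rnorm(800), d$time_months, d$event) - 0.5), 0.05)
  expect_error(c_index(1, 5, 0), "no comparable pairs")
})

test_that("the c-index is invariant under strictly monotone risk transforms", {
  d <- sim_survival(150, beta = -1, censor_frac = 0.3, seed = 6)
  risk <- -d$x
  c0 <- c_index(risk, d$time_months, d$event)
  expect_equal(c_index(exp(risk), d$time_months, d$event), c0)
  expect_equal(c_index(rank(risk), d$time_months, d$event), c0)
})

test_that("the c-index agrees with the survival package on censored data", {
  d <- sim_survival(300, beta = -1.2, censor_frac = 0.3, seed = 7)
  risk <- -d$x
  ours <- c_index(risk, d$time_months, d$event)
  ref <- survival::concordance(survival::Surv(time_months, event) ~ risk,
                               data = d, reverse = TRUE)$concordance
  expect_equal(ours, ref)
})

test_that("cross-validated c-index separates strong predictors from noise", {
  d <- sim_survival(300, beta = -3, censor_frac = 0.2, seed = 8)
  cv <- crossvalidated_cindex(d, "x", k = 10, seed = 1)
  expect_gt(cv$cindex, 0.7)
  d$pure_noise <- rnorm(300)
  cvn <- crossvalidated_cindex(d, "pure_noise", k = 10, seed = 1)
  expect_lt(abs(cvn$cindex - 0.5), 0.05)
  cv2 <- crossvalidated_cindex(d, "x", k = 10, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$cindex, cv2$cindex)
})

test_that("paired bootstrap comparison behaves at its fixed points", {
  d <- sim_survival(200, beta = -2, censor_frac = 0.2, seed = 9)
  risk <- -d$x
  self <- compare_cindex(risk, risk, d$time_months, d$event, n_boot = 50,
                         seed = 2)
  expect_identical(self$delta, 0)
  expect_equal(self$p_value, 1)
  noise <- rnorm(200)
  ab <- compare_cindex(risk, noise, d$time_months, d$event, n_boot = 400,
                       seed = 3)
  ba <- compare_cindex(noise, risk, d$time_months, d$event, n_boot = 400,
                       seed = 3)
  expect_equal(ab$delta, -ba$delta)
  expect_gt(ab$delta, 0)
  expect_lt(ab$p_value, 0.05)
})

test_that("Kaplan-Meier estimates match the product-limit hand example", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km_at(km, 1), 2 / 3)
  expect_equal(km_at(km, 2), 1 / 3)
  expect_equal(km_at(km, 3), 1 / 3)
  expect_equal(km_at(km, 0.5), 1)
  # all censored: survival never drops
  expect_true(all(km_estimate(1:5, rep(0, 5))$surv == 1))
  # no censoring: KM equals the empirical survivor function
  set.seed(10)
  t <- rexp(100)
  km2 <- km_estimate(t, rep(1, 100))
  expect_equal(km_at(km2, sort(t)), 1 - seq_len(100) / 100)
})

test_that("median-split curves separate a prognostic feature", {
  set.seed(11)
  d <- data.frame(time_months = rexp(100, 0.05), event = 1L)
  d$feature <- -d$time_months  # low feature = long survival
  ks <- km_median_split(d, "feature")
  expect_lt(ks$p_value, 0.01)
  expect_equal(ks$n_low + ks$n_high, 100)
  # identical duplicated groups: no separation at all
  d2 <- data.frame(time_months = rep(c(1, 2, 3, 4), 2),
                   event = rep(1L, 8),
                   feature = rep(c(0, 0, 0, 0, 1, 1, 1, 1)))
  expect_lt(km_median_split(d2, "feature")$logrank_chisq, 1e-10)
  expect_error(km_median_split(transform(d, feature = 1), "feature"),
               "constant")
})

test_that("rank-sum test matches exact enumeration and has power", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 2 / 6)  # 1 extreme ordering of C(4,2) = 6, two-sided
  expect_equal(wilcoxon_rank_sum(rep(3, 4), rep(3, 5))$p_value, 1)
  # shift of 2 SD, n = 30 per group: rejection in >= 90% of replicates
  hits <- 0
  for (r in 1:200) {
    set.seed(r)
    if (wilcoxon_rank_sum(rnorm(30), rnorm(30, mean = 2))$p_value < 0.05) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 200, 0.9)
})

test_that("recurrence patterns follow the isodose coverage rule", {
  expect_identical(classify_recurrence_pattern(0.95), "in-field")
  expect_identical(classify_recurrence_pattern(0.50), "marginal")
  expect_identical(classify_recurrence_pattern(0.10), "out-field")
  expect_identical(classify_recurrence_pattern(c(0.20, 0.80)),
                   c("marginal", "marginal"))
  expect_error(classify_recurrence_pattern(1.2), "0, 1")
})
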