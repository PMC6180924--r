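sim_xy <- function(n, p_noise = 4, beta = -1.5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * (1 + p_noise)), n,
              dimnames = list(NULL, c("causal", paste0("noise", 1:p_noise))))
  t_event <- rexp(n, rate = 0.05 * exp(beta * x[, "causal"]))
  cens <- runif(n, 0, quantile(t_event, 0.9) * 4)
  list(x = x, time = pmin(t_event, cens), event = as.integer(t_event <= cens))
}

test_that("penalties above the path maximum shrink every coefficient to zero", {
  d <- sim_xy(150)
  xs <- scale(d$x)
  beta <- fit_lasso_cox(xs, d$time, d$event, lambda = 10)
  expect_true(all(beta == 0))
})

test_that("an unpenalized fit matches the Cox partial-likelihood maximizer", {
  d <- sim_xy(200, p_noise = 1)
  xs <- scale(d$x)
  beta <- fit_lasso_cox(xs, d$time, d$event, lambda = 0)
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ xs)$coefficients
  expect_lt(max(abs(beta - ref)), 1e-4)
})

test_that("a duplicated column never carries real weight alongside its twin", {
  d <- sim_xy(150, p_noise = 2)
  x <- cbind(d$x, dup = d$x[, "causal"])
  xs <- scale(x)
  path <- glmnet::glmnet(xs, survival::Surv(d$time, d$event), family = "cox",
                         standardize = FALSE)
  b <- as.matrix(path$beta)
  # the L1 penalty puts the shared signal on one of the two identical
  # columns; the other stays at solver-tolerance dust at every penalty
  smaller <- pmin(abs(b["causal", ]), abs(b["dup", ]))
  larger <- pmax(abs(b["causal", ]), abs(b["dup", ]))
  expect_lt(max(smaller), 1e-2)
  expect_true(all(smaller <= larger))
})

test_that("constant columns are dropped with a warning", {
  d <- sim_xy(100, p_noise = 1)
  x <- cbind(d$x, flat = 1)
  expect_warning(beta <- fit_lasso_cox(x, d$time, d$event, lambda = 0.1),
                 "flat")
  expect_equal(beta[["flat"]], 0)
})

test_that("stability selection is reproducible and ranks the causal feature first", {
  d <- sim_xy(150, p_noise = 4, beta = -2, seed = 5)
  s1 <- stability_select(d$x, d$time, d$event, n_runs = 30, seed = 42)
  s2 <- stability_select(d$x, d$time, d$event, n_runs = 30, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$selected, s2$selected)
  expect_true("causal" %in% s1$selected)
  expect_true(all(s1$frequency["causal"] >= s1$frequency))
})

test_that("a zero-variance feature is never selected", {
  d <- sim_xy(100, p_noise = 2, beta = -2)
  x <- cbind(d$x, flat = 0)
  s <- stability_select(x, d$time, d$event, n_runs = 10, seed = 7)
  expect_equal(s$frequency[["flat"]], 0)
})

test_that("folds-only resampling is available and deterministic", {
  d <- sim_xy(120, p_noise = 2, beta = -2)
  s1 <- stability_select(d$x, d$time, d$event, n_runs = 5, seed = 3,
                         resample = "none")
  s2 <- stability_select(d$x, d$time, d$event, n_runs = 5, seed = 3,
                         resample = "none")
  expect_identical(s1$counts, s2$counts)
})

test_that("independent-noise selection frequencies stay below one half", {
  d <- sim_xy(500, p_noise = 4, beta = -2, seed = 9)
  s <- stability_select(d$x, d$time, d$event, n_runs = 100, seed = 11)
  noise_names <- grep("^noise", names(s$frequency), value = TRUE)
  expect_true(all(s$frequency[noise_names] < 0.5))
})

test_that("correlation screens match rank and product-moment conventions", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_screen(a, 2 * a + 1, "pearson"), 1)
  expect_equal(correlation_screen(a, 2 * a + 1, "spearman"), 1)
  expect_equal(correlation_screen(a, a^3, "spearman"), 1)
  expect_lt(correlation_screen(a, a^3, "pearson"), 1)
  # hand: d = (1,-1,1,-1) between rank vectors -> 1 - 6*4/(4*15) = 0.6
  expect_equal(correlation_screen(c(1, 2, 3, 4), c(2, 1, 4, 3), "spearman"),
               0.6)
  expect_warning(r <- correlation_screen(rep(1, 5), a), "constant")
  expect_true(is.na(r))
})

test_that("the correlation report flags redundant and clinical-linked pairs", {
  set.seed(2)
  f <- data.frame(a = rnorm(50))
  f$b <- f$a + rnorm(50, sd = 0.1)     # strongly rank-correlated pair
  f$c <- rnorm(50)
  clin <- data.frame(age = f$a * 3 + rnorm(50, sd = 0.5), idx = rnorm(50))
  rep_ <- correlation_report(f, clin)
  expect_true(rep_$flagged[rep_$a == "a" & rep_$b == "b"])
  expect_true(rep_$flagged[rep_$a == "a" & rep_$b == "age" &
                             rep_$method == "pearson"])
  expect_false(any(rep_$flagged[rep_$a == "c" & rep_$b == "idx"]))
})
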