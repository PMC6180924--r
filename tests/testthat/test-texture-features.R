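test_that("first-order features match hand-computed moments", {
  f <- first_order_features(vol1d(c(1, 2, 3)), full_mask(c(3, 1, 1)))
  expect_equal(f[["SUVmean"]], 2)
  expect_equal(f[["SUVmax"]], 3)
  expect_equal(f[["skewness"]], 0)

  f2 <- first_order_features(vol1d(c(0, 0, 0, 4)), full_mask(c(4, 1, 1)))
  expect_equal(f2[["SUVmean"]], 1)
  expect_equal(f2[["skewness"]], 2 / sqrt(3))  # m2 = 3, m3 = 6

  expect_warning(f3 <- first_order_features(vol1d(rep(2, 4)),
                                            full_mask(c(4, 1, 1))),
                 "zero-variance")
  expect_true(is.na(f3[["skewness"]]) && is.na(f3[["kurtosis"]]))
})

test_that("run percentage and LILRE match the six-voxel hand example", {
  q <- qvoi_from_levels(array(c(1, 1, 2, 2, 2, 1), c(6, 1, 1)), B = 2)
  g <- glrlm_build(q, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(run_percentage(g), 0.5)          # 3 runs / 6 voxels
  expect_equal(lilre(g), 7.25 / 3)              # (4/1 + 9/4 + 1/1) / 3
})

test_that("run-length feature limits behave as expected", {
  # single run of N voxels at level 1: LILRE = N^2, run percentage = 1/N
  one_run <- glrlm_build(qvoi_from_levels(array(1, c(7, 1, 1)), B = 3),
                         directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(lilre(one_run), 49)
  expect_equal(run_percentage(one_run), 1 / 7)
  # all-distinct levels: every run has length 1 in every direction
  q <- qvoi_from_levels(array(sample(64), c(4, 4, 4)), B = 64)
  expect_equal(run_percentage(glrlm_build(q)), 1.0)
})

test_that("intensity flip decreases LILRE when long runs sit at low levels", {
  low_long <- qvoi_from_levels(array(c(2, 2, 1, 1, 1, 2), c(6, 1, 1)), B = 2)
  flipped <- qvoi_from_levels(array(c(1, 1, 2, 2, 2, 1), c(6, 1, 1)), B = 2)
  d1 <- matrix(c(1L, 0L, 0L), 1)
  expect_lt(lilre(glrlm_build(flipped, d1)), lilre(glrlm_build(low_long, d1)))
})

test_that("GLCM features match hand counts", {
  q <- qvoi_from_levels(array(c(1, 2, 1, 2), c(4, 1, 1)), B = 2)
  g <- glcm_build(q, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(g$P[1, 2], 0.5)
  expect_equal(g$P[2, 1], 0.5)
  f <- glcm_features(g)
  expect_equal(f[["contrast"]], 1.0)
  expect_equal(f[["homogeneity"]], 0.5)

  const <- glcm_features(qvoi_from_levels(array(1, c(3, 3, 1)), B = 2))
  expect_equal(const[["homogeneity"]], 1)
  expect_equal(const[["contrast"]], 0)

  for (seed in 1:5) {
    expect_gte(glcm_features(random_qvoi(seed))[["contrast"]], 0)
  }
})

test_that("coarseness matches the oracle and caps on constant VOIs", {
  expect_equal(ngtdm_coarseness(qvoi_from_levels(array(1, c(4, 4, 4)), B = 2)),
               1e6)
  q <- qvoi_from_levels(array(c(1, 3, 1), c(3, 1, 1)), B = 3)
  bf <- bf_ngtdm(q$level_array, B = 3)
  expect_equal(ngtdm_coarseness(q), 1 / (1e-6 + sum(bf$p * bf$s)))
  expect_equal(ngtdm_coarseness(q), 1 / (1e-6 + 10 / 3))  # hand: s1=4, s3=2
})

test_that("smoother lesion borders give larger coarseness", {
  feat_at_sigma <- function(sig) {
    spec <- phantom_spec(grid_shape = c(24, 24, 18), tumor_radius_mm = 12,
                         border_sigma_mm = sig, noise_sd = 0)
    v <- generate_phantom(spec)
    extract_features(v, segment_isocontour(v))[["coarseness"]]
  }
  c2 <- feat_at_sigma(2)
  c4 <- feat_at_sigma(4)
  expect_gt(c4, c2)
  # a sharp noise-free border leaves a constant plateau VOI: capped at 1/eps
  expect_equal(feat_at_sigma(0), 1e6)
})

test_that("size-zone LILZE matches hand-enumerated zones", {
  expect_equal(glszm_lilze(qvoi_from_levels(array(1, c(3, 2, 1)), B = 2)), 36)
  two <- array(0, c(5, 1, 1))
  two[1, 1, 1] <- 2; two[5, 1, 1] <- 2
  expect_equal(glszm_lilze(qvoi_from_levels(two, B = 2)), 0.25)
})

test_that("code similarity is the pairwise identity probability", {
  expect_equal(code_similarity(qvoi_from_levels(array(1, c(3, 3, 3)), B = 2)), 1)
  expect_equal(code_similarity(c("a", "b", "c")), 0)
  expect_equal(code_similarity(c("a", "a", "b")), 1 / 3)
  expect_error(code_similarity("a"), "at least 2")
})

test_that("SUV peak equals brute-force sphere placement", {
  # coarse spacing: the 1 cm^3 sphere holds a single voxel
  v <- vol1d(c(1, 5, 2), spacing = c(10, 10, 10))
  expect_equal(suv_peak(v, full_mask(c(3, 1, 1), c(10, 10, 10))), 5)
  # uniform uptake
  u <- image_volume(array(3, c(4, 4, 4)), c(3, 3, 3))
  expect_equal(suv_peak(u, full_mask(c(4, 4, 4), c(3, 3, 3))), 3)
  # hot corner, spacing 5 mm: exhaustive enumeration oracle
  set.seed(8)
  a <- array(runif(125), c(5, 5, 5))
  a[1:2, 1:2, 1:2] <- a[1:2, 1:2, 1:2] + 10
  vol <- image_volume(a, c(5, 5, 5))
  mask <- full_mask(c(5, 5, 5), c(5, 5, 5))
  r_mm <- 10 * (3 / (4 * pi))^(1 / 3)
  best <- -Inf
  for (x in 1:5) for (y in 1:5) for (z in 1:5) {
    tot <- 0; cnt <- 0
    for (nx in 1:5) for (ny in 1:5) for (nz in 1:5) {
      d2 <- (5 * (nx - x))^2 + (5 * (ny - y))^2 + (5 * (nz - z))^2
      if (d2 <= r_mm^2) { tot <- tot + a[nx, ny, nz]; cnt <- cnt + 1 }
    }
    best <- max(best, tot / cnt)
  }
  expect_equal(suv_peak(vol, mask), best)
})

test_that("SUL peak applies the James lean-body-mass formula", {
  lbm <- 1.10 * 80 - 128 * (80 / 180)^2
  expect_equal(sul_peak(6, 80, 180, "M"), 6 * lbm / 80)
  lbm_f <- 1.07 * 60 - 148 * (60 / 165)^2
  expect_equal(sul_peak(6, 60, 165, "F"), 6 * lbm_f / 60)
  expect_true(is.na(sul_peak(6, NA, 180, "M")))
})

test_that("feature extraction is deterministic and robust to degenerate VOIs", {
  spec <- phantom_spec(grid_shape = c(20, 20, 14), tumor_radius_mm = 10,
                       noise_sd = 0.5, seed = 31)
  v <- generate_phantom(spec)
  m <- segment_isocontour(v)
  expect_identical(extract_features(v, m), extract_features(v, m))
  # constant plateau VOI: skewness/kurtosis NA, nothing crashes
  flat <- generate_phantom(phantom_spec(grid_shape = c(12, 12, 10),
                                        tumor_radius_mm = 8,
                                        border_sigma_mm = 0, noise_sd = 0))
  fm <- segment_isocontour(flat)
  f <- extract_features(flat, fm)
  expect_true(is.na(f[["skewness"]]))
  expect_equal(f[["coarseness"]], 1e6)
  expect_equal(f[["code_similarity"]], 1)
})

test_that("per-direction averaging is exposed as an aggregation mode", {
  spec <- phantom_spec(grid_shape = c(16, 16, 12), tumor_radius_mm = 9,
                       noise_sd = 0.5, seed = 17)
  v <- generate_phantom(spec)
  m <- segment_isocontour(v)
  f_sum <- extract_features(v, m, aggregation = "sum")
  f_avg <- extract_features(v, m, aggregation = "average")
  expect_false(isTRUE(all.equal(f_sum[["LILRE"]], f_avg[["LILRE"]])))
  expect_equal(f_sum[["SUVmean"]], f_avg[["SUVmean"]])
})
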