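test_that("Bland-Altman statistics match hand computation", {
  id <- paired_measurements(1:5, 1:5)
  ba <- bland_altman(id)
  expect_equal(c(ba$mean_diff, ba$sd_diff, ba$loa_lower, ba$loa_upper),
               c(0, 0, 0, 0))
  shifted <- bland_altman(paired_measurements(1:5 + 2.5, 1:5))
  expect_equal(shifted$mean_diff, 2.5)
  expect_equal(shifted$sd_diff, 0)
  # d = {-1, 0, 1}: mean 0, sample SD 1 (n-1 denominator), LoA = +/- 1.96
  ba3 <- bland_altman(paired_measurements(c(0, 1, 2), c(1, 1, 1)))
  expect_equal(ba3$mean_diff, 0)
  expect_equal(ba3$sd_diff, 1)
  expect_equal(ba3$loa_lower, -1.96)
  expect_equal(ba3$loa_upper, 1.96)
  expect_equal(ba3$ci_mean_lower, -1.96 / sqrt(3))
  expect_error(bland_altman(paired_measurements(1, 1)), "n >= 2")
})

test_that("Bland-Altman limits satisfy their defining identity", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    pm <- paired_measurements(rnorm(n, 10, 3), rnorm(n, 10, 3))
    ba <- bland_altman(pm)
    expect_equal(ba$loa_lower, ba$mean_diff - 1.96 * ba$sd_diff)
    expect_equal(ba$loa_upper, ba$mean_diff + 1.96 * ba$sd_diff)
    expect_true(ba$loa_lower <= ba$mean_diff && ba$mean_diff <= ba$loa_upper)
  }
})

test_that("Pearson correlation agrees with cor.test as oracle", {
  set.seed(8)
  for (rep in 1:15) {
    n <- sample(5:80, 1)
    x <- rnorm(n); y <- 0.6 * x + rnorm(n)
    res <- pearson_with_ci(paired_measurements(x, y))
    ct <- stats::cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
    expect_equal(c(res$ci_lower, res$ci_upper), as.numeric(ct$conf.int),
                 tolerance = 1e-9)
  }
  # perfect linear relations
  expect_equal(pearson_with_ci(paired_measurements(2 * (1:10) + 1, 1:10))$r, 1)
  expect_equal(pearson_with_ci(paired_measurements(-(1:10), 1:10))$r, -1)
  expect_error(pearson_with_ci(paired_measurements(rep(1, 10), 1:10)),
               "zero variance")
  expect_error(pearson_with_ci(paired_measurements(1:3, 3:1)), "n >= 4")
})

test_that("Pearson r is invariant to positive affine rescaling", {
  set.seed(13)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- pearson_with_ci(paired_measurements(x, y))$r
  r1 <- pearson_with_ci(paired_measurements(5 * x + 3, 0.2 * y - 7))$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("ICC(2,1) equals the two-way ANOVA mean-squares oracle", {
  set.seed(21)
  icc_oracle <- function(m) {
    # independent route through stats::aov
    n <- nrow(m); k <- ncol(m)
    df <- data.frame(y = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  for (rep in 1:25) {
    m <- matrix(rnorm(26 * 2, 10, 2), 26, 2)
    m[, 2] <- m[, 2] + rnorm(26, 0.5, 1)
    res <- icc_2_1(m)
    expect_equal(res$icc, icc_oracle(m), tolerance = 1e-10)
    expect_true(res$ci_lower <= res$icc && res$icc <= res$ci_upper)
  }
  # perfect agreement
  x <- rnorm(10)
  perfect <- icc_2_1(paired_measurements(x, x))
  expect_equal(perfect$icc, 1)
  expect_error(icc_2_1(matrix(1, 10, 2)), "degenerate")
  expect_error(icc_2_1(matrix(rnorm(8), 4, 2)), "at least 5")
})

test_that("absolute agreement penalizes a rater offset", {
  set.seed(33)
  x <- rnorm(40, 10, 2)
  y <- x + rnorm(40, 0, 0.5)
  base <- icc_2_1(paired_measurements(x, y))$icc
  shifted <- icc_2_1(paired_measurements(x, y + 3))$icc
  expect_lt(shifted, base)
})

test_that("ICC approaches Pearson r for exchangeable raters at large n", {
  set.seed(55)
  n <- 10000
  z <- rnorm(n)
  x <- z + rnorm(n, 0, 0.8)
  y <- z + rnorm(n, 0, 0.8)   # same means and variances by construction
  icc <- icc_2_1(paired_measurements(x, y))$icc
  r <- stats::cor(x, y)
  expect_lt(abs(icc - r), 0.02)
})

test_that("Fisher r-to-Z comparison matches the closed form", {
  # r1 = 0.8 vs r2 = 0.5 with n = 103 each: z = 3.884 (frozen from the
  # formula (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)))
  fc <- fisher_compare(0.8, 103, 0.5, 103)
  expect_equal(fc$z_stat, (atanh(0.8) - atanh(0.5)) / sqrt(2 / 100),
               tolerance = 1e-12)
  expect_equal(fc$z_stat, 3.884181, tolerance = 1e-6)
  expect_equal(fc$p_value, 2 * pnorm(-abs(fc$z_stat)))
  # equal coefficients: z = 0, p = 1
  same <- fisher_compare(0.6, 30, 0.6, 50)
  expect_equal(same$z_stat, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry under group swap
  a <- fisher_compare(0.7, 40, 0.3, 60)
  b <- fisher_compare(0.3, 60, 0.7, 40)
  expect_equal(a$z_stat, -b$z_stat)
  expect_equal(a$p_value, b$p_value)
  expect_error(fisher_compare(1, 30, 0.5, 30), "Fisher transform")
  expect_error(fisher_compare(0.5, 3, 0.5, 30), ">= 4")
})

test_that("Fisher comparison p-values are uniform under the null", {
  set.seed(99)
  n <- 30; reps <- 10000
  sim_r <- function() {
    x <- matrix(rnorm(n * reps), n)
    y <- matrix(rnorm(n * reps), n)
    xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
    colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
  }
  r1 <- sim_r(); r2 <- sim_r()
  z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  p <- 2 * pnorm(-abs(z))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("platform evaluation reports the full analysis grid", {
  set.seed(17)
  segs <- lapply(1:6, function(i) {
    truth <- phantom_truth(small_spec(stenosis_severity = 0.3 + 0.05 * i))
    reference_area_profile(truth, 0.5)
  })
  rep_id <- evaluate_platform(segs, segs)
  expect_s3_class(rep_id, "latm_report")
  expect_named(rep_id$analyses, c("volume", "area", "stenotic_area"))
  for (an in rep_id$analyses) expect_named(an, c("lumen", "plaque"))
  # identical test and reference: per-plane area blocks agree exactly
  for (an in c("area", "stenotic_area")) for (blk in rep_id$analyses[[an]]) {
    expect_equal(blk$bland_altman$mean_diff, 0, tolerance = 1e-9)
    expect_equal(blk$bland_altman$sd_diff, 0, tolerance = 1e-9)
    expect_equal(blk$icc$icc, 1, tolerance = 1e-9)
  }
  # volume blocks compare the interval-sum convention (test side) against
  # Simpson integration (reference side); on identical profiles the
  # difference is the half-plane overhang at the two segment ends
  for (blk in rep_id$analyses$volume) {
    expect_equal(blk$n, 6L)
    overhang <- 0.5 * 2 * max(pi * 9)  # interval x mean end areas, bound
    expect_lt(abs(blk$bland_altman$mean_diff), overhang)
  }
  expect_identical(rep_id$icc_comparison_method, "fisher-z-on-icc")
  expect_error(evaluate_platform(segs[1:2], segs[1:3]), "same number")
})
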