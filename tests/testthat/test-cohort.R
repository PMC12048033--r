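test_that("cww_means averages map values per atlas pattern", {
  dims <- c(4, 4, 1)
  atlas <- array(0L, dims); atlas[1:2, 1, 1] <- 1L; atlas[3:4, 1, 1] <- 2L
  m1 <- array(5e-3, dims)
  m2 <- array(0, dims); m2[1, 1, 1] <- 2e-3; m2[2, 1, 1] <- 4e-3
  tab <- cww_means(list(m1, m2), atlas)
  expect_equal(tab$cww1, c(5e-3, 3e-3))
  expect_equal(tab$cww2, c(5e-3, 0))
  expect_error(cww_means(list(m1), array(0L, dims)), "no labelled voxels")
  expect_error(cww_means(list(array(1, c(2, 2, 2))), atlas), "does not match")
})

test_that("cww_means on the phantom reproduces the generator algebra", {
  pop <- make_phantom_population(phantom_config(
    grid_shape = c(10, 10, 10), n_subjects = 6, k_true = 2,
    noise_sigma = 0, seed = 8))
  tab <- cww_means(pop$truth$mpsi_true, pop$truth$labels_true)
  base <- pop$truth$config$base_mpsi
  # block patterns are indicators: mean over pattern k = base * H[k, i]
  expect_equal(tab$cww1, base * pop$truth$H_true[1, ], tolerance = 1e-12)
  expect_equal(tab$cww2, base * pop$truth$H_true[2, ], tolerance = 1e-12)
})

test_that("IQR filter uses interpolated quartiles and is idempotent", {
  r <- iqr_filter(1:9)
  expect_equal(unname(r$fences), c(-3, 13))
  expect_length(r$excluded, 0)
  r2 <- iqr_filter(c(1:9, 100))
  expect_equal(r2$excluded, 10L)
  expect_equal(r2$retained, 1:9)
  r3 <- iqr_filter(rep(4, 6))
  expect_length(r3$excluded, 0)
  expect_error(iqr_filter(1:3), "at least 4")
  # refiltering only ever tightens: the second pass retains a subset, and
  # when the first pass excludes nothing the filter is exactly idempotent
  set.seed(30)
  for (i in 1:10) {
    v <- rnorm(60, 3e-3, 2e-4)
    v[1:2] <- v[1:2] + c(2e-3, -2e-3)   # clear outliers
    kept <- iqr_filter(v)$retained
    expect_true(all(iqr_filter(kept)$retained %in% kept))
    clean <- iqr_filter(kept)$retained
    if (length(iqr_filter(clean)$excluded) == 0)
      expect_identical(iqr_filter(clean)$retained, clean)
  }
})

test_that("GLM returns standardized betas with null behaviour and errors", {
  set.seed(31)
  n <- 120
  tab <- data.frame(cww1 = rnorm(n), age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    bpf = rnorm(n))
  res <- fit_glm(tab, "cww1", c("age", "sex", "bpf"), iqr_exclude = FALSE)
  expect_true(all(abs(res$beta) < 0.3))
  # standardized beta of a pure effect equals the correlation
  tab$cww2 <- 0.6 * scale(tab$age) + sqrt(1 - 0.36) * rnorm(n)
  res2 <- fit_glm(tab, "cww2", "age", iqr_exclude = FALSE)
  expect_equal(res2$beta, cor(tab$cww2, tab$age)[1], tolerance = 1e-10)
  tab$age2 <- tab$age
  expect_error(fit_glm(tab, "cww1", c("age", "age2")), "collinear")
})

test_that("degenerate two-cohort mixed model matches pooled OLS", {
  pop <- make_phantom_population(phantom_config(
    grid_shape = c(8, 8, 8), n_subjects = 120, k_true = 2, noise_sigma = 0,
    coeff_effects = list(age = 0.4), n_cohorts = 2,
    cohort_offsets = c(0, 0), seed = 33))
  tab <- cww_means(pop$truth$mpsi_true, pop$truth$labels_true, pop$subjects)
  glm_res <- fit_glm(tab, "cww1", c("age", "sex", "bpf"))
  mix_res <- fit_mixed(tab, "cww1", c("age", "sex", "bpf"))
  expect_equal(mix_res$beta, glm_res$beta, tolerance = 0.02)
  # with only two groups the REML intercept SD is noisy around 0
  expect_lt(mix_res$cohort_sd[1], 0.3)
  expect_error(fit_mixed(subset(tab, cohort == "cohort1"), "cww1", "age"),
               "one cohort")
})

test_that("cohort offsets appear as random-intercept variance, not fixed-effect bias", {
  pop <- make_phantom_population(phantom_config(
    grid_shape = c(8, 8, 8), n_subjects = 160, k_true = 2, noise_sigma = 0,
    coeff_effects = list(age = 0.4), n_cohorts = 2,
    cohort_offsets = c(-0.5, 0.5), seed = 34))
  tab <- cww_means(pop$truth$mpsi_true, pop$truth$labels_true, pop$subjects)
  mix <- fit_mixed(tab, "cww1", c("age", "sex", "bpf"))
  expect_gt(mix$cohort_sd[1], 0.05)
  # global z-standardization of the outcome absorbs the cohort variance,
  # attenuating the planted 0.4 by 1/sqrt(1 + 0.25)
  expect_lt(abs(mix$beta[mix$predictor == "age"] - 0.4 / sqrt(1.25)), 0.15)
})

test_that("aberrant-flow criteria follow the two z-score rules strictly", {
  set.seed(35)
  n <- 40
  base <- matrix(rnorm(n * 3, 3e-3, 1e-4), n, 3,
                 dimnames = list(NULL, paste0("cww", 1:3)))
  tab <- as.data.frame(base)
  tab$subject_id <- sprintf("s%02d", 1:n)
  rep0 <- detect_aberrant(tab, grouping = "pooled")
  z <- rep0$z
  # flags must be exactly reconstructable from the returned z matrix
  expect_equal(rep0$report$criterion_i, rowSums(abs(z) > 3) >= 1)
  expect_equal(rep0$report$criterion_ii, rowSums(abs(z) > 2) >= 2)
  expect_equal(rep0$report$aberrant,
               rep0$report$criterion_i | rep0$report$criterion_ii)

  # planted: one extreme single-pattern subject, one double-moderate subject
  # (values set against the pre-modification mean/SD so the realized z-scores
  # land above 3, and between 2 and 3, respectively)
  tab2 <- tab
  tab2$cww1[1] <- mean(tab$cww1) + 5.0 * sd(tab$cww1)
  tab2$cww2[2] <- mean(tab$cww2) + 2.6 * sd(tab$cww2)
  tab2$cww3[2] <- mean(tab$cww3) + 2.6 * sd(tab$cww3)
  rep2 <- detect_aberrant(tab2, grouping = "pooled")
  expect_true(rep2$report$criterion_i[1])
  expect_true(rep2$report$aberrant[1])
  expect_true(rep2$report$criterion_ii[2])
  # a single ~2.5 SD deviation alone does not flag
  tab3 <- tab
  tab3$cww2[3] <- tab3$cww2[3] + 3e-4
  rep3 <- detect_aberrant(tab3, grouping = "pooled")
  z3 <- rep3$z[3, ]
  if (sum(abs(z3) > 2) == 1 && all(abs(z3) < 3))
    expect_false(rep3$report$aberrant[3])
  expect_error(detect_aberrant(tab[1:5, ], grouping = "pooled"),
               "fewer than 10")
})

test_that("null aberrant rate matches the analytic rate of the two criteria", {
  set.seed(36)
  n <- 1e5; k <- 10
  tab <- as.data.frame(matrix(rnorm(n * k), n, k))
  names(tab) <- paste0("cww", 1:k)
  rate <- mean(detect_aberrant(tab, grouping = "pooled")$report$aberrant)
  p2 <- 2 * pnorm(-2); p3 <- 2 * pnorm(-3)
  p_ok <- (1 - p2)^k + k * (p2 - p3) * (1 - p2)^(k - 1)
  expected <- 1 - p_ok
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rate - expected), 3 * se + 2e-3)
})

test_that("Fisher exact matches brute-force enumeration and the convention table", {
  expect_equal(fisher_exact(c(1, 1, 1, 1)), 1)
  set.seed(37)
  for (i in 1:40) {
    tb <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(fisher_exact(tb),
                 fisher_brute(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "nonnegative")
  # one-sided equals the upper hypergeometric tail
  expect_equal(fisher_exact(c(5, 33, 0, 252), sided = "greater"),
               sum(dhyper(5:38, 38, 252, 5)), tolerance = 1e-12)
})
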