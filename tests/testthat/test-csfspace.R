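make_two_class <- function(n_side = 10, seed = 1, sd_md = 1e-4, sd_fa = 0.02) {
  set.seed(seed)
  dims <- c(n_side, n_side, n_side)
  csf <- array(FALSE, dims)
  csf[1:(n_side / 2), , ] <- TRUE
  md <- array(0.8e-3 + rnorm(prod(dims), 0, sd_md), dims)
  fa <- array(0.4 + rnorm(prod(dims), 0, sd_fa), dims)
  md[csf] <- 3e-3 + rnorm(sum(csf), 0, sd_md)
  fa[csf] <- 0.05 + rnorm(sum(csf), 0, sd_fa)
  fa <- pmin(pmax(fa, 0), 1)
  list(fa = fa, md = md, csf = csf, mask = array(TRUE, dims))
}

test_that("two-tissue EM separates well-separated clusters almost surely", {
  fx <- make_two_class()
  seg <- segment_two_tissue(fx$fa, fx$md, fx$mask, seed = 0)
  post <- seg$csf_fraction$values
  # >= 99% of voxels assigned > 0.99 posterior to the generating class
  conf <- ifelse(fx$csf, post, 1 - post)
  expect_gt(mean(conf > 0.99), 0.99)
  # fractions sum to one inside the mask
  expect_equal(seg$csf_fraction$values + seg$wm_fraction$values,
               array(1, dim(post)), tolerance = 1e-12)
})

test_that("EM agrees with the mclust reference on the same features", {
  suppressPackageStartupMessages(require(mclust, quietly = TRUE))
  fx <- make_two_class(n_side = 6, seed = 2)
  seg <- segment_two_tissue(fx$fa, fx$md, fx$mask, seed = 0)
  feat <- cbind(as.vector(fx$fa), as.vector(fx$md))
  mc <- mclust::Mclust(scale(feat), G = 2, modelNames = "VVV",
                       verbose = FALSE)
  # align classes by mean MD and compare hard assignments
  mc_csf <- which.max(tapply(feat[, 2], mc$classification, mean))
  agree <- mean((seg$csf_fraction$values > 0.5) ==
                  (mc$classification == mc_csf))
  expect_gt(agree, 0.99)
})

test_that("degenerate segmentation inputs error", {
  dims <- c(4, 4, 4)
  const <- array(1, dims)
  expect_error(segment_two_tissue(const, const, array(TRUE, dims)),
               "degenerate")
})

test_that("pseudo-T1 contrast conventions", {
  dims <- c(2, 2, 2)
  csf <- array(c(1, 0, 0.5, 0, 1, 0.25, 0, 1), dims)
  wm <- 1 - csf
  pt <- pseudo_t1(scalar_map(csf, "CSF_FRACTION"),
                  scalar_map(wm, "WM_FRACTION"))
  expect_equal(pt$values, 2 * wm + csf)
  expect_equal(pt$values[1, 1, 1], 1)   # pure CSF
  expect_equal(pt$values[2, 1, 1], 2)   # pure tissue
  expect_equal(pt$values[1, 2, 1], 1.5) # half/half
})

test_that("group CSF mask applies both strict thresholds", {
  dims <- c(2, 2, 1)
  mk <- function(v) scalar_map(array(v, dims), "CSF_FRACTION")
  # voxel [1,1,1]: fraction 0.8 in 7/10 subjects -> in (70% > 65%)
  # voxel [2,1,1]: 0.8 in 6/10 -> out; voxel [1,2,1]: exactly 0.7 -> out
  maps <- lapply(1:10, function(i) {
    v <- array(0, dims)
    v[1, 1, 1] <- if (i <= 7) 0.8 else 0.1
    v[2, 1, 1] <- if (i <= 6) 0.8 else 0.1
    v[1, 2, 1] <- 0.7
    mk(v)
  })
  m <- group_csf_mask(maps)
  expect_true(m[1, 1, 1])
  expect_false(m[2, 1, 1])
  expect_false(m[1, 2, 1])
  expect_error(group_csf_mask(list(mk(array(0, dims)),
                                   scalar_map(array(0, c(3, 3, 1))))),
               "grid mismatch")
})

test_that("group mask is monotone in added super-threshold subjects", {
  set.seed(4)
  dims <- c(6, 6, 6)
  maps <- lapply(1:9, function(i)
    scalar_map(array(runif(prod(dims)), dims), "CSF_FRACTION"))
  m1 <- group_csf_mask(maps)
  m2 <- group_csf_mask(c(maps, list(
    scalar_map(array(0.95, dims), "CSF_FRACTION"))))
  expect_true(all(m2[m1]))
})

test_that("low-fraction fill averages satisfactory neighbours iteratively", {
  dims <- c(3, 3, 3)
  mask <- array(FALSE, dims)
  # centre voxel plus its 6 face neighbours
  mask[2, 2, 2] <- TRUE
  nb <- rbind(c(1, 2, 2), c(3, 2, 2), c(2, 1, 2), c(2, 3, 2),
              c(2, 2, 1), c(2, 2, 3))
  mask[nb] <- TRUE
  fr <- array(1, dims); fr[2, 2, 2] <- 0.2
  mp <- array(0, dims); mp[nb] <- (1:6) * 1e-3
  res <- fill_low_fraction(mp, fr, mask, threshold = 0.7)
  expect_equal(res$filled[2, 2, 2], 3.5e-3)
  expect_equal(res$filled[nb], (1:6) * 1e-3)  # donors untouched
  expect_false(any(res$unfillable))

  # no low-fraction voxels: identity
  res2 <- fill_low_fraction(mp, array(1, dims), mask, 0.7)
  expect_equal(res2$filled, mp)

  # isolated island with no satisfactory voxel anywhere: unfillable
  mask3 <- array(FALSE, dims); mask3[1, 1, 1] <- TRUE
  res3 <- fill_low_fraction(mp, array(0, dims), mask3, 0.7)
  expect_true(res3$unfillable[1, 1, 1])

  # two-step fill: a chain where the far voxel is reached via the near one
  mask4 <- array(FALSE, c(5, 1, 1)); mask4[1:3, 1, 1] <- TRUE
  fr4 <- array(c(1, 0.1, 0.1, 0, 0), c(5, 1, 1))
  mp4 <- array(c(4e-3, 0, 0, 0, 0), c(5, 1, 1))
  res4 <- fill_low_fraction(mp4, fr4, mask4, 0.7)
  expect_equal(res4$filled[2, 1, 1], 4e-3)
  expect_equal(res4$filled[3, 1, 1], 4e-3)
})

test_that("in-mask smoothing preserves constants and out-of-mask voxels", {
  set.seed(6)
  dims <- c(8, 8, 8)
  mask <- array(runif(prod(dims)) > 0.4, dims)
  vals <- array(rnorm(prod(dims), 5, 2), dims)
  sm <- smooth_in_mask(vals, mask, fwhm_mm = 3, voxel_size = c(2, 2, 2))
  expect_equal(sm[!mask], vals[!mask])
  # convex combination: output within [min, max] of in-mask inputs
  expect_gte(min(sm[mask]), min(vals[mask]) - 1e-12)
  expect_lte(max(sm[mask]), max(vals[mask]) + 1e-12)
  # constants are exactly preserved
  cm <- smooth_in_mask(array(7, dims), mask, 3, c(1, 1, 1))
  expect_equal(cm[mask], rep(7, sum(mask)), tolerance = 1e-12)
  # fwhm = 0 is the identity
  expect_equal(smooth_in_mask(vals, mask, 0, c(1, 1, 1)), vals)
  expect_error(smooth_in_mask(vals, array(FALSE, dims), 3), "empty mask")
})

test_that("full chain on a noiseless anisotropic phantom recovers the planted CSF domain", {
  pop <- make_phantom_population(phantom_config(
    grid_shape = c(10, 10, 10), n_subjects = 4, k_true = 2,
    noise_sigma = 0, anisotropic = TRUE, seed = 9))
  mask <- array(TRUE, c(10, 10, 10))
  fracs <- lapply(pop$dwi, function(d) {
    tf <- fit_pseudo_tensor(d)
    segment_two_tissue(fractional_anisotropy(tf),
                       mean_pseudo_diffusivity(tf), mask)$csf_fraction
  })
  gm <- group_csf_mask(fracs)
  expect_identical(gm, pop$truth$csf_mask)
})
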