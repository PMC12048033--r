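test_that("noiseless tensor fit recovers planted tensors to 1e-8", {
  set.seed(7)
  dims <- c(4, 4, 4)
  tens <- array(0, c(dims, 6))
  tm <- matrix(tens, ncol = 6)
  for (v in seq_len(prod(dims))) tm[v, ] <- random_psd6()
  tf <- tensor_field(array(tm, c(dims, 6)))
  dwi <- forward_signal(tf, default_scheme(), s0 = 80, noise_sigma = 0)
  fit <- fit_pseudo_tensor(dwi)
  expect_lt(max(abs(fit$tensor - tf$tensor)), 1e-8)
  expect_lt(max(abs(fit$s0 - 80)), 1e-8)
  expect_false(any(fit$floored))
})

test_that("constant signal across b fits a zero tensor", {
  sch <- default_scheme()
  sig <- array(42, c(3, 3, 3, length(sch$bvals)))
  fit <- fit_pseudo_tensor(dwi_stack(sig, sch))
  expect_lt(max(abs(fit$tensor)), 1e-12)
  expect_equal(as.vector(fit$s0), rep(42, 27))
})

test_that("fit preconditions: volume count and direction rank", {
  tf <- isotropic_tensor_field(array(1e-3, c(2, 2, 2)))
  dwi <- forward_signal(tf, default_scheme(), s0 = 10)
  expect_error(fit_pseudo_tensor(dwi, b_max = 10), "fewer than 7")
  # coplanar directions: all in the x-y plane
  ang <- seq(0, pi, length.out = 8)[1:7]
  sch <- acquisition_scheme(c(0, rep(100, 7)),
                            rbind(c(0, 0, 0),
                                  cbind(cos(ang), sin(ang), 0)))
  dwi2 <- forward_signal(tf, sch, s0 = 10)
  expect_error(fit_pseudo_tensor(dwi2), "rank-deficient|coplanar")
})

test_that("log-linear fit residuals are orthogonal to the design", {
  set.seed(11)
  sch <- default_scheme()
  sig <- array(rexp(2 * 2 * 2 * 8, rate = 1 / 50), c(2, 2, 2, 8))
  dwi <- dwi_stack(sig, sch)
  fit <- fit_pseudo_tensor(dwi)
  X <- cbind(1,
             -sch$bvals * sch$bvecs[, 1]^2,
             -sch$bvals * sch$bvecs[, 2]^2,
             -sch$bvals * sch$bvecs[, 3]^2,
             -2 * sch$bvals * sch$bvecs[, 1] * sch$bvecs[, 2],
             -2 * sch$bvals * sch$bvecs[, 1] * sch$bvecs[, 3],
             -2 * sch$bvals * sch$bvecs[, 2] * sch$bvecs[, 3])
  for (v in 1:3) {
    idx <- arrayInd(v, c(2, 2, 2))
    y <- log(sig[idx[1], idx[2], idx[3], ])
    beta <- c(log(fit$s0[idx[1], idx[2], idx[3]]),
              fit$tensor[idx[1], idx[2], idx[3], ])
    resid <- y - X %*% beta
    expect_lt(max(abs(crossprod(X, resid))), 1e-10)
  }
})

test_that("nonpositive signals are floored and flagged", {
  sch <- default_scheme()
  sig <- array(50, c(2, 2, 2, 8))
  sig[1, 1, 1, 5] <- 0
  fit <- fit_pseudo_tensor(dwi_stack(sig, sch))
  expect_true(fit$floored[1, 1, 1])
  expect_false(any(fit$floored[-1]))
  expect_true(all(is.finite(fit$tensor)))
})

test_that("mean pseudo-diffusivity is trace/3 and matches eigenvalue mean", {
  tens <- array(0, c(1, 1, 1, 6))
  tens[1, 1, 1, ] <- c(1e-3, 2e-3, 3e-3, 0, 0, 0)
  expect_equal(mean_pseudo_diffusivity(tensor_field(tens))$values[1, 1, 1],
               2e-3)
  set.seed(3)
  for (i in 1:20) {
    v <- random_psd6()
    t1 <- array(v, c(1, 1, 1, 6))
    md <- mean_pseudo_diffusivity(tensor_field(t1))$values[1, 1, 1]
    expect_equal(md, mean(eigen(sym_from6(v), symmetric = TRUE,
                                only.values = TRUE)$values),
                 tolerance = 1e-12)
  }
})

test_that("analytic tensor eigenvalues match the eigen() oracle", {
  set.seed(5)
  M <- t(replicate(50, random_psd6()))
  got <- tensor_eigenvalues(M)
  for (i in 1:50) {
    expect_equal(as.vector(got[i, ]),
                 eigen(sym_from6(M[i, ]), symmetric = TRUE,
                       only.values = TRUE)$values,
                 tolerance = 1e-9)
  }
})

test_that("FA has its closed-form values and stays in [0,1]", {
  mk <- function(v) tensor_field(array(v, c(1, 1, 1, 6)))
  expect_equal(fractional_anisotropy(mk(c(2e-3, 2e-3, 2e-3, 0, 0, 0))
                                     )$values[1, 1, 1], 0)
  expect_equal(fractional_anisotropy(mk(c(5e-3, 0, 0, 0, 0, 0))
                                     )$values[1, 1, 1], 1)
  expect_equal(fractional_anisotropy(mk(c(3e-3, 2e-3, 1e-3, 0, 0, 0))
                                     )$values[1, 1, 1], sqrt(3 / 14),
               tolerance = 1e-12)
  expect_equal(fractional_anisotropy(mk(rep(0, 6)))$values[1, 1, 1], 0)
  set.seed(8)
  for (i in 1:30) {
    fa <- fractional_anisotropy(mk(random_psd6()))$values[1, 1, 1]
    expect_gte(fa, 0); expect_lte(fa, 1)
  }
})

test_that("MPsi is invariant to joint rotation of tensor and directions", {
  set.seed(13)
  v <- random_psd6()
  S <- sym_from6(v)
  qrr <- qr(matrix(rnorm(9), 3)); R <- qr.Q(qrr)
  Sr <- R %*% S %*% t(R)
  vr <- c(Sr[1, 1], Sr[2, 2], Sr[3, 3], Sr[1, 2], Sr[1, 3], Sr[2, 3])
  m1 <- mean_pseudo_diffusivity(tensor_field(array(v, c(1, 1, 1, 6))))
  m2 <- mean_pseudo_diffusivity(tensor_field(array(vr, c(1, 1, 1, 6))))
  expect_equal(m1$values, m2$values, tolerance = 1e-10)
})

test_that("nrmse is zero for perfect fits and r/m for constant residuals", {
  tf <- isotropic_tensor_field(array(2e-3, c(3, 3, 3)))
  dwi <- forward_signal(tf, default_scheme(), s0 = 60, noise_sigma = 0)
  fit <- fit_pseudo_tensor(dwi)
  nr <- nrmse(dwi, fit, shell_b = 100)
  expect_lt(max(abs(nr$values)), 1e-10)
  # add a constant residual r on the b=100 shell of the *measured* data
  r <- 0.7
  sig2 <- dwi$signal
  shell <- which(dwi$scheme$bvals == 100)
  pred <- sig2[, , , shell]
  sig2[, , , shell] <- sig2[, , , shell] + r
  dwi2 <- dwi_stack(sig2, dwi$scheme)
  nr2 <- nrmse(dwi2, fit, shell_b = 100)   # model from the clean fit
  expect_equal(as.vector(nr2$values),
               rep(r / (mean(pred[1, 1, 1]) + r), 27), tolerance = 1e-10)
  expect_error(nrmse(dwi, fit, shell_b = 123), "no volumes")
})

test_that("nrmse grows monotonically with pulsatile tensor jitter", {
  tf <- isotropic_tensor_field(array(3e-3, c(4, 4, 4)))
  med <- sapply(c(0, 0.1, 0.3), function(pj) {
    dwi <- forward_signal(tf, default_scheme(), s0 = 100, noise_sigma = 0,
                          seed = 21, pulsatility = pj)
    fit <- fit_pseudo_tensor(dwi)
    median(nrmse(dwi, fit, shell_b = 100)$values)
  })
  expect_true(all(diff(med) > 0))
})

test_that("velocity covariance decomposes and round-trips Psi", {
  dims <- c(2, 2, 2)
  psi <- isotropic_tensor_field(array(3e-3, dims))
  d0 <- isotropic_tensor_field(array(1e-3, dims))
  v <- velocity_covariance(psi, d0, tau_d = 2)
  # tau_d = 2: V = Psi - D elementwise here
  expect_equal(v$tensor, psi$tensor - d0$tensor)
  expect_equal(velocity_covariance(psi, psi, tau_d = 0.5)$tensor,
               array(0, c(dims, 6)))
  # algebraic inverse: Psi' = (tau_d / 2) V + D reproduces Psi exactly
  expect_equal((2 / 2) * v$tensor + d0$tensor, psi$tensor)
  expect_error(velocity_covariance(psi, d0, tau_d = 0), "positive")
})
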