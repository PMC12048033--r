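# Pseudo-diffusion tensor estimation from low-b DWI.
#
# At low diffusion weightings the CSF signal follows a monoexponential decay
# S = S0 * exp(-b g' Psi g) where Psi is the apparent ("pseudo-diffusion")
# tensor combining velocity-distribution covariance and molecular diffusion.
# The fit is ordinary least squares on the log signal against the 7-parameter
# design (ln S0 plus the 6 unique tensor elements).

# design row per volume, tensor element order (xx, yy, zz, xy, xz, yz)
tensor_design <- function(bvals, bvecs) {
  g <- bvecs
  cbind(1,
        -bvals * g[, 1]^2,
        -bvals * g[, 2]^2,
        -bvals * g[, 3]^2,
        -2 * bvals * g[, 1] * g[, 2],
        -2 * bvals * g[, 1] * g[, 3],
        -2 * bvals * g[, 2] * g[, 3])
}

#' Fit the pseudo-diffusion tensor by log-linear least squares
#'
#' Per voxel, ordinary least squares of the log signal on the 7-parameter
#' tensor design. Multiple b = 0 volumes are averaged into a single reference
#' before fitting. Nonpositive signals are floored to `1e-6 * s0` (with s0
#' approximated by the voxel's reference signal) and the voxel is flagged in
#' `floored`; stored tensors are never eigenvalue-clamped, and voxels whose
#' fitted tensor has a negative eigenvalue are flagged `nonphysical`.
#'
#' @param dwi A [dwi_stack].
#' @param b_max Use only volumes with b <= `b_max` (s/mm^2). Default `Inf`.
#' @param fit_mask Optional logical 3D array restricting the fit.
#' @return A [tensor_field] with `s0`, `fit_mask`, `floored` and
#'   `nonphysical` per-voxel flags.
#' @examples
#' ph <- isotropic_tensor_field(array(3e-3, c(3, 3, 3)))
#' dwi <- forward_signal(ph, default_scheme(), s0 = 100, noise_sigma = 0)
#' fit <- fit_pseudo_tensor(dwi)
#' max(abs(fit$tensor - ph$tensor))  # ~1e-18
#' @export
fit_pseudo_tensor <- function(dwi, b_max = Inf, fit_mask = NULL) {
  stopifnot(inherits(dwi, "dwi_stack"))
  sch <- dwi$scheme
  use <- sch$bvals <= b_max
  if (sum(use) < 7L)
    stop("fewer than 7 usable volumes with b <= b_max; ",
         "need >= 6 distinct directions plus a reference")
  bvals <- sch$bvals[use]
  bvecs <- sch$bvecs[use, , drop = FALSE]
  dims <- dim(dwi$signal)[1:3]
  nvox <- prod(dims)
  sig <- matrix(dwi$signal, nrow = nvox)[, use, drop = FALSE]

  bmin <- min(bvals)
  is_ref <- bvals == bmin
  if (bmin == 0 && sum(is_ref) > 1L) {
    ref <- rowMeans(sig[, is_ref, drop = FALSE])
    sig <- cbind(ref, sig[, !is_ref, drop = FALSE])
    bvecs <- rbind(0, bvecs[!is_ref, , drop = FALSE])
    bvals <- c(0, bvals[!is_ref])
  }
  X <- tensor_design(bvals, bvecs)
  qx <- qr(X)
  if (qx$rank < 7L)
    stop("rank-deficient tensor design: gradient directions are coplanar ",
         "or fewer than 6 distinct directions (rank ", qx$rank, ")")

  if (is.null(fit_mask)) fit_mask <- array(TRUE, dims)
  fit_mask <- array(as.logical(fit_mask), dims)
  idx <- which(fit_mask)
  S <- t(sig[idx, , drop = FALSE])            # volumes x voxels

  s0_proxy <- S[which.min(bvals), ]
  s0_proxy[s0_proxy <= 0] <- mean(S[S > 0], na.rm = TRUE)
  bad <- S <= 0
  floored_vox <- colSums(bad) > 0L
  if (any(bad)) {
    eps <- matrix(1e-6 * s0_proxy, nrow = nrow(S), ncol = ncol(S),
                  byrow = TRUE)
    S[bad] <- eps[bad]
  }
  B <- qr.coef(qx, log(S))                     # 7 x voxels

  tens <- array(NA_real_, c(dims, 6))
  tmat <- matrix(tens, ncol = 6L)
  tmat[idx, ] <- t(B[2:7, , drop = FALSE])
  tens <- array(tmat, c(dims, 6))
  s0 <- array(NA_real_, dims)
  s0[idx] <- exp(B[1, ])
  floored <- array(FALSE, dims)
  floored[idx] <- floored_vox

  out <- tensor_field(tens, s0 = s0, fit_mask = fit_mask, floored = floored,
                      voxel_size = dwi$voxel_size, affine = dwi$affine)
  ev <- tensor_eigenvalues(out)
  np <- array(FALSE, dims)
  np[idx] <- ev[idx, 3] < 0
  out$nonphysical <- np
  out
}

#' Eigenvalues of every tensor in a field
#'
#' Vectorized analytic eigendecomposition of the symmetric 3 x 3 tensors
#' (trigonometric solution of the characteristic cubic).
#'
#' @param field A [tensor_field] (or a D x 6 matrix of unique elements).
#' @return A D x 3 matrix of eigenvalues in decreasing order (D = number of
#'   voxels, row-major over the grid in R array order).
#' @export
tensor_eigenvalues <- function(field) {
  m <- if (inherits(field, "tensor_field")) tensor_mat(field) else as.matrix(field)
  a11 <- m[, 1]; a22 <- m[, 2]; a33 <- m[, 3]
  a12 <- m[, 4]; a13 <- m[, 5]; a23 <- m[, 6]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- which(p > 0)
  if (length(nz)) {
    pn <- p[nz]
    b11 <- (a11[nz] - q[nz]) / pn; b22 <- (a22[nz] - q[nz]) / pn
    b33 <- (a33[nz] - q[nz]) / pn
    b12 <- a12[nz] / pn; b13 <- a13[nz] / pn; b23 <- a23[nz] / pn
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- q[nz] + 2 * pn * cos(phi)
    l3[nz] <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    l2[nz] <- 3 * q[nz] - l1[nz] - l3[nz]
  }
  cbind(l1, l2, l3)
}

#' Mean pseudo-diffusivity map
#'
#' trace(Psi)/3 per voxel: the scalar measure of CSF effective motility,
#' analogous to mean diffusivity at high b-values.
#'
#' @param field A fitted [tensor_field].
#' @return A [scalar_map] with role `MPSI` (mm^2/s).
#' @export
mean_pseudo_diffusivity <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  m <- tensor_mat(field)
  v <- array((m[, 1] + m[, 2] + m[, 3]) / 3, dim(field$tensor)[1:3])
  scalar_map(v, "MPSI", voxel_size = field$voxel_size, affine = field$affine)
}

#' Fractional anisotropy map
#'
#' Standard normalized eigenvalue dispersion, computed from rotational
#' invariants; exactly 0 for the zero tensor (the 0/0 case is guarded).
#'
#' @param field A fitted [tensor_field].
#' @return A [scalar_map] with role `FA` (unitless).
#' @export
fractional_anisotropy <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  m <- tensor_mat(field)
  md <- (m[, 1] + m[, 2] + m[, 3]) / 3
  off2 <- m[, 4]^2 + m[, 5]^2 + m[, 6]^2
  num <- (m[, 1] - md)^2 + (m[, 2] - md)^2 + (m[, 3] - md)^2 + 2 * off2
  den <- m[, 1]^2 + m[, 2]^2 + m[, 3]^2 + 2 * off2
  fa <- sqrt(1.5 * num / den)
  fa[den == 0] <- 0
  fa <- pmin(fa, 1)  # guard rounding at the FA = 1 boundary
  scalar_map(array(fa, dim(field$tensor)[1:3]), "FA",
             voxel_size = field$voxel_size, affine = field$affine)
}

# internal: model-predicted signal matrix (volumes x voxels) for given volumes
predict_signal <- function(field, bvals, bvecs, idx) {
  m <- tensor_mat(field)[idx, , drop = FALSE]
  g <- bvecs
  # quadratic form g' Psi g per (volume, voxel)
  qf <- outer(g[, 1]^2, m[, 1]) + outer(g[, 2]^2, m[, 2]) +
    outer(g[, 3]^2, m[, 3]) + 2 * outer(g[, 1] * g[, 2], m[, 4]) +
    2 * outer(g[, 1] * g[, 3], m[, 5]) + 2 * outer(g[, 2] * g[, 3], m[, 6])
  sweep(exp(-bvals * qf), 2L, field$s0[idx], "*")
}

#' Normalized root-mean-square fit error on one b-shell
#'
#' Per voxel, the RMSE between model-predicted and measured signal over the
#' shell's volumes, normalized by the voxel's mean measured signal on that
#' shell. In ungated acquisitions this residual carries cardiac/respiratory
#' variability of CSF flow in addition to noise.
#'
#' @param dwi The [dwi_stack] the field was fitted from.
#' @param field The fitted [tensor_field].
#' @param shell_b b-value (s/mm^2) selecting the shell.
#' @return A [scalar_map] with role `NRMSE`; voxels with zero mean shell
#'   signal are `NaN` (flagged, not fatal).
#' @export
nrmse <- function(dwi, field, shell_b) {
  stopifnot(inherits(dwi, "dwi_stack"), inherits(field, "tensor_field"))
  sel <- dwi$scheme$bvals == shell_b
  if (!any(sel)) stop("no volumes at shell b = ", shell_b)
  dims <- dim(dwi$signal)[1:3]
  idx <- which(field$fit_mask)
  sig <- matrix(dwi$signal, nrow = prod(dims))[idx, sel, drop = FALSE]
  pred <- t(predict_signal(field, dwi$scheme$bvals[sel],
                           dwi$scheme$bvecs[sel, , drop = FALSE], idx))
  rmse <- sqrt(rowMeans((sig - pred)^2))
  msig <- rowMeans(sig)
  val <- rmse / msig
  val[msig == 0] <- NaN
  out <- array(NA_real_, dims)
  out[idx] <- val
  scalar_map(out, "NRMSE", voxel_size = field$voxel_size,
             affine = field$affine)
}

#' Velocity-covariance component of the pseudo-diffusion tensor
#'
#' Decomposes Psi ~ (tau_d / 2) V + D: given the molecular diffusion tensor D
#' and the diffusion time tau_d, returns V = (2 / tau_d) (Psi - D), the
#' covariance of the intravoxel velocity distribution (mm^2/s^2).
#'
#' @param psi Fitted pseudo-diffusion [tensor_field].
#' @param d_ref Molecular diffusion [tensor_field] on the same grid.
#' @param tau_d Diffusion time of the sequence, seconds (> 0).
#' @return A [tensor_field] holding V.
#' @export
velocity_covariance <- function(psi, d_ref, tau_d) {
  stopifnot(inherits(psi, "tensor_field"), inherits(d_ref, "tensor_field"))
  if (tau_d <= 0) stop("tau_d must be positive")
  if (!identical(dim(psi$tensor), dim(d_ref$tensor)))
    stop("grids of psi and d_ref do not match")
  tensor_field((2 / tau_d) * (psi$tensor - d_ref$tensor),
               s0 = psi$s0, fit_mask = psi$fit_mask,
               voxel_size = psi$voxel_size, affine = psi$affine)
}
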