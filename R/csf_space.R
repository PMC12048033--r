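# Construction of the common CSF analysis domain: two-tissue segmentation
# from diffusion contrast, pseudo-T1 synthesis, the group CSF mask rule,
# low-fraction fill, and within-mask smoothing.

#' Group CSF mask rule parameters
#'
#' @param fraction_threshold CSF partial-volume threshold (strict `>`),
#'   default 0.7.
#' @param subject_proportion Proportion of subjects that must exceed it
#'   (strict `>`), default 0.65.
#' @param fwhm_mm Smoothing kernel full width at half maximum, mm, default 3.
#' @return A list of class `group_mask_spec`.
#' @export
group_mask_spec <- function(fraction_threshold = 0.7,
                            subject_proportion = 0.65,
                            fwhm_mm = 3.0) {
  stopifnot(fraction_threshold > 0, fraction_threshold < 1,
            subject_proportion > 0, subject_proportion < 1, fwhm_mm >= 0)
  structure(list(fraction_threshold = fraction_threshold,
                 subject_proportion = subject_proportion,
                 fwhm_mm = fwhm_mm),
            class = "group_mask_spec")
}

# bivariate normal log-density from mean (2) and covariance (2x2)
ldmvn2 <- function(x, mu, S) {
  dS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  xc1 <- x[, 1] - mu[1]; xc2 <- x[, 2] - mu[2]
  q <- (S[2, 2] * xc1^2 - 2 * S[1, 2] * xc1 * xc2 + S[1, 1] * xc2^2) / dS
  -log(2 * pi) - 0.5 * log(dS) - 0.5 * q
}

#' Two-tissue segmentation from diffusion contrast
#'
#' Two-class Gaussian-mixture EM on the bivariate (FA, MD) features within
#' the brain mask, exploiting the intrinsic diffusion contrast between CSF
#' (high MD, low FA) and parenchyma. The class with the higher mean MD is
#' labelled CSF. Posterior probabilities are returned as partial-volume
#' fraction maps that sum to 1 at every in-mask voxel. Initialization is by
#' feature-space k-means under a fixed seed, so results are deterministic.
#'
#' @param fa FA [scalar_map] (or 3D array).
#' @param md Mean (pseudo-)diffusivity [scalar_map] (or 3D array), mm^2/s.
#' @param brain_mask Logical 3D array.
#' @param seed Integer seed for the k-means initialization.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return List with `csf_fraction` and `wm_fraction` [scalar_map]s (NA
#'   outside the mask) and the fitted mixture (`means`, `covs`, `weights`,
#'   `loglik`, `n_iter`).
#' @export
segment_two_tissue <- function(fa, md, brain_mask, seed = 0L,
                               max_iter = 500L, tol = 1e-8) {
  fa_v <- map_values(fa); md_v <- map_values(md)
  stopifnot(identical(dim(fa_v), dim(md_v)),
            identical(dim(fa_v), dim(brain_mask)))
  idx <- which(brain_mask)
  feat <- cbind(fa_v[idx], md_v[idx])
  if (nrow(unique(feat)) < 2L)
    stop("degenerate input: fewer than 2 distinct feature values in mask")
  fz <- scale(feat)
  fz[, apply(feat, 2, stats::sd) == 0] <- 0

  set.seed(seed)
  km <- stats::kmeans(fz, centers = 2L, nstart = 5L)
  z <- cbind(km$cluster == 1L, km$cluster == 2L) * 1

  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    nk <- colSums(z)
    if (any(nk < 2)) stop("EM degenerated: a class emptied at iteration ", it)
    w <- nk / nrow(fz)
    ld <- matrix(0, nrow(fz), 2)
    for (g in 1:2) {
      mu <- colSums(z[, g] * fz) / nk[g]
      xc <- sweep(fz, 2, mu)
      S <- crossprod(xc * z[, g], xc) / nk[g] + diag(1e-8, 2)
      ld[, g] <- log(w[g]) + ldmvn2(fz, mu, S)
    }
    mx <- pmax(ld[, 1], ld[, 2])
    ll <- sum(mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx)))
    z <- exp(ld - mx)
    z <- z / rowSums(z)
    if (is.finite(loglik) &&
        abs(ll - loglik) <= tol * (abs(loglik) + tol)) break
    loglik <- ll
    if (it == max_iter)
      stop("EM did not converge in ", max_iter,
           " iterations (last log-likelihood ", format(ll), ")")
  }
  md_means <- c(sum(z[, 1] * feat[, 2]) / sum(z[, 1]),
                sum(z[, 2] * feat[, 2]) / sum(z[, 2]))
  csf_cls <- which.max(md_means)
  dims <- dim(fa_v)
  csf <- array(NA_real_, dims); wm <- array(NA_real_, dims)
  csf[idx] <- z[, csf_cls]
  wm[idx] <- z[, 3 - csf_cls]
  vs <- if (inherits(fa, "scalar_map")) fa$voxel_size else c(1, 1, 1)
  list(csf_fraction = scalar_map(csf, "CSF_FRACTION", voxel_size = vs),
       wm_fraction = scalar_map(wm, "WM_FRACTION", voxel_size = vs),
       md_means = md_means, n_iter = it, loglik = loglik)
}

#' Pseudo-T1-weighted image from partial-volume fractions
#'
#' Linear combination 2 * wm + 1 * csf: tissue brighter than CSF, mimicking
#' T1 contrast for registration purposes. Deterministic.
#'
#' @param csf_fraction,wm_fraction Partial-volume [scalar_map]s in \[0, 1\].
#' @return A [scalar_map] with role `PSEUDO_T1`.
#' @export
pseudo_t1 <- function(csf_fraction, wm_fraction) {
  c_v <- map_values(csf_fraction); w_v <- map_values(wm_fraction)
  stopifnot(identical(dim(c_v), dim(w_v)))
  vs <- if (inherits(csf_fraction, "scalar_map"))
    csf_fraction$voxel_size else c(1, 1, 1)
  scalar_map(2 * w_v + 1 * c_v, "PSEUDO_T1", voxel_size = vs)
}

#' Group CSF mask
#'
#' A voxel enters the common CSF domain iff its CSF fraction exceeds
#' `fraction_threshold` in strictly more than `subject_proportion` of the
#' subjects (both comparisons strict).
#'
#' @param csf_fractions List of per-subject CSF-fraction [scalar_map]s on one
#'   grid.
#' @param spec A [group_mask_spec].
#' @return Logical 3D array.
#' @export
group_csf_mask <- function(csf_fractions, spec = group_mask_spec()) {
  stopifnot(length(csf_fractions) >= 2L)
  dims <- dim(map_values(csf_fractions[[1]]))
  count <- array(0L, dims)
  for (f in csf_fractions) {
    v <- map_values(f)
    if (!identical(dim(v), dims)) stop("grid mismatch across subjects")
    count <- count + (!is.na(v) & v > spec$fraction_threshold)
  }
  count / length(csf_fractions) > spec$subject_proportion
}

# 26-connected neighbour offsets
neighbour_offsets <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

# shift a 3D array by integer offset, padding with `fill`
shift3 <- function(a, d, fill = 0) {
  dims <- dim(a)
  out <- array(fill, dims)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dims[ax]
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(n - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(n + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(n + d[ax])
    }
    if (abs(d[ax]) >= n) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Fill low-CSF-fraction voxels from satisfactory neighbours
#'
#' In-mask voxels whose CSF fraction falls below `threshold` receive the mean
#' map value of their 26-connected in-mask neighbours with fraction >=
#' `threshold`. The fill is iterative: newly filled voxels become donors,
#' until no fillable voxel remains. Satisfactory voxels are never altered.
#'
#' @param mpsi Map to fill ([scalar_map] or 3D array).
#' @param csf_fraction CSF-fraction map on the same grid.
#' @param mask Logical 3D array (the group CSF mask).
#' @param threshold Fraction threshold, default 0.7.
#' @return List: `filled` ([scalar_map] or array matching the input type),
#'   `unfillable` (logical array flagging in-mask voxels that could not be
#'   filled; reported, not fatal).
#' @export
fill_low_fraction <- function(mpsi, csf_fraction, mask, threshold = 0.7) {
  v <- map_values(mpsi)
  fr <- map_values(csf_fraction)
  stopifnot(identical(dim(v), dim(fr)), identical(dim(v), dim(mask)))
  ok <- mask & !is.na(fr) & fr >= threshold          # donors
  todo <- mask & !ok
  offs <- neighbour_offsets()
  val <- v
  val[todo] <- NA_real_
  while (any(todo)) {
    s <- array(0, dim(v)); cnt <- array(0, dim(v))
    for (r in seq_len(nrow(offs))) {
      dv <- shift3(ifelse(ok, val, 0), offs[r, ])
      dc <- shift3(ok * 1, offs[r, ])
      s <- s + dv; cnt <- cnt + dc
    }
    fillable <- todo & cnt > 0
    if (!any(fillable)) break
    val[fillable] <- s[fillable] / cnt[fillable]
    ok <- ok | fillable
    todo <- todo & !fillable
  }
  out <- v
  out[mask] <- val[mask]
  if (inherits(mpsi, "scalar_map")) {
    m <- mpsi; m$values <- out
    list(filled = m, unfillable = todo)
  } else {
    list(filled = out, unfillable = todo)
  }
}

#' Gaussian smoothing restricted to a mask
#'
#' Gaussian kernel with sigma = fwhm / sqrt(8 ln 2) per axis (mm converted to
#' voxels), with weights restricted to in-mask voxels and renormalized to sum
#' to 1 at each target voxel (so constants are preserved and no out-of-mask
#' signal bleeds in). Out-of-mask voxels are untouched. Implemented as the
#' ratio of separable convolutions of `x * mask` and `mask`.
#'
#' @param map [scalar_map] or 3D array.
#' @param mask Logical 3D array; must be nonempty.
#' @param fwhm_mm Kernel FWHM in mm; 0 is the identity.
#' @param voxel_size mm per axis (taken from the map when it is a
#'   [scalar_map]).
#' @return Smoothed map of the same type as the input.
#' @export
smooth_in_mask <- function(map, mask, fwhm_mm = 3,
                           voxel_size = NULL) {
  v <- map_values(map)
  stopifnot(identical(dim(v), dim(mask)), fwhm_mm >= 0)
  if (!any(mask)) stop("empty mask")
  if (is.null(voxel_size))
    voxel_size <- if (inherits(map, "scalar_map")) map$voxel_size else c(1, 1, 1)
  if (fwhm_mm == 0) return(map)
  num <- ifelse(mask, v, 0)
  den <- mask * 1
  for (ax in 1:3) {
    sig <- fwhm_mm / sqrt(8 * log(2)) / voxel_size[ax]
    r <- max(1L, ceiling(3 * sig))
    w <- exp(-(seq(-r, r))^2 / (2 * sig^2))
    w <- w / sum(w)
    na <- array(0, dim(v)); da <- array(0, dim(v))
    for (t in seq(-r, r)) {
      d <- c(0L, 0L, 0L); d[ax] <- t
      na <- na + w[t + r + 1] * shift3(num, d)
      da <- da + w[t + r + 1] * shift3(den, d)
    }
    num <- na; den <- da
  }
  out <- v
  out[mask] <- num[mask] / den[mask]
  if (inherits(map, "scalar_map")) {
    m <- map; m$values <- out; m
  } else out
}
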