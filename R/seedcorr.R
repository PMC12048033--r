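# Hypothesis-driven seed-based covariance mapping of mean pseudo-diffusivity
# across subjects, with Benjamini-Hochberg FDR control.

#' Seed region of interest
#'
#' @param name ROI name.
#' @param voxel_indices n x 3 integer matrix of grid coordinates (1-based).
#' @return Object of class `seed_roi`.
#' @export
seed_roi <- function(name, voxel_indices) {
  voxel_indices <- matrix(as.integer(voxel_indices), ncol = 3L)
  if (nrow(voxel_indices) == 0L) stop("ROI must be nonempty")
  structure(list(name = name, voxel_indices = voxel_indices),
            class = "seed_roi")
}

# stack of maps -> voxels x subjects matrix
stack_matrix <- function(mpsi_stack) {
  v1 <- map_values(mpsi_stack[[1]])
  out <- vapply(mpsi_stack, function(m) {
    v <- map_values(m)
    if (!identical(dim(v), dim(v1))) stop("stack grids do not match")
    as.vector(v)
  }, numeric(length(v1)))
  out
}

#' Per-subject mean map value over a seed ROI
#'
#' @param mpsi_stack List of per-subject [scalar_map]s on one grid.
#' @param roi A [seed_roi].
#' @param mask Optional logical 3D array; all ROI voxels must fall inside it.
#' @return Numeric vector, one unweighted ROI mean per subject.
#' @export
roi_mean <- function(mpsi_stack, roi, mask = NULL) {
  stopifnot(inherits(roi, "seed_roi"))
  dims <- dim(map_values(mpsi_stack[[1]]))
  if (any(roi$voxel_indices < 1L) ||
      any(sweep(roi$voxel_indices, 2L, dims, ">") ))
    stop("ROI indices outside the grid")
  lin <- roi$voxel_indices[, 1] +
    dims[1] * (roi$voxel_indices[, 2] - 1L) +
    dims[1] * dims[2] * (roi$voxel_indices[, 3] - 1L)
  if (!is.null(mask) && !all(mask[lin]))
    stop("ROI '", roi$name, "' extends outside the mask")
  X <- stack_matrix(mpsi_stack)
  colMeans(X[lin, , drop = FALSE])
}

#' Voxelwise seed correlation map
#'
#' Pearson correlation across subjects between a seed value vector and each
#' in-mask voxel, with the two-sided p-value from the t transform at N - 2
#' degrees of freedom. Voxels with zero variance across subjects get NA.
#'
#' @param seed_values Per-subject numeric vector (e.g. from [roi_mean]).
#' @param mpsi_stack List of per-subject [scalar_map]s.
#' @param mask Logical 3D array restricting the computation.
#' @return List of [scalar_map]s `r` (role `CORRELATION_R`) and `p` (role
#'   `PVALUE`).
#' @export
seed_correlation <- function(seed_values, mpsi_stack, mask) {
  n <- length(mpsi_stack)
  if (n < 3L) stop("need at least 3 subjects")
  if (length(seed_values) != n)
    stop("seed_values length does not match the stack")
  if (stats::sd(seed_values) == 0) stop("seed values have zero variance")
  X <- stack_matrix(mpsi_stack)
  idx <- which(mask)
  V <- X[idx, , drop = FALSE]
  vc <- V - rowMeans(V)
  sc <- seed_values - mean(seed_values)
  denom <- sqrt(rowSums(vc^2)) * sqrt(sum(sc^2))
  r <- as.vector(vc %*% sc) / denom
  r[denom == 0 | rowSums(vc^2) == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  dims <- dim(mask)
  rmap <- array(NA_real_, dims); pmap <- array(NA_real_, dims)
  rmap[idx] <- r; pmap[idx] <- p
  vs <- if (inherits(mpsi_stack[[1]], "scalar_map"))
    mpsi_stack[[1]]$voxel_size else c(1, 1, 1)
  list(r = scalar_map(rmap, "CORRELATION_R", voxel_size = vs),
       p = scalar_map(pmap, "PVALUE", voxel_size = vs))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity; significance is
#' `adjusted p < q` (strict). When maps for several seed ROIs are tested,
#' pool their voxel p-values into one call (the strictest defensible reading
#' of a joint correction across ROIs); a per-ROI correction at `q / n_roi` is
#' available via the `bonferroni_rois` argument.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NA allowed,
#'   propagated).
#' @param q FDR level, default 0.01.
#' @param bonferroni_rois Optional integer: divide `q` by this ROI count
#'   instead of pooling (the per-ROI option).
#' @return List: `adjusted` (same length as `pvalues`) and `significant`
#'   (logical).
#' @export
fdr_adjust <- function(pvalues, q = 0.01, bonferroni_rois = NULL) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  thr <- if (is.null(bonferroni_rois)) q else q / bonferroni_rois
  list(adjusted = adj, significant = !is.na(adj) & adj < thr)
}
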