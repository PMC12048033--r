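#' 3D scalar map with a role tag
#'
#' The common currency between pipeline stages: a 3D array tagged with what it
#' measures. Roles and units: `MPSI` mean pseudo-diffusivity (mm^2/s), `FA`
#' fractional anisotropy (unitless, \[0,1\]), `NRMSE` normalized fit error
#' (unitless, >= 0), `CSF_FRACTION`/`WM_FRACTION` partial volumes (\[0,1\]),
#' `PSEUDO_T1` synthetic T1-like contrast, `CORRELATION_R`, `PVALUE`.
#'
#' @param values 3D numeric array.
#' @param role One of the role strings above.
#' @param voxel_size mm per axis (length 3).
#' @param affine 4 x 4 grid-to-world transform.
#' @return Object of class `scalar_map`.
#' @export
scalar_map <- function(values, role = c("MPSI", "FA", "NRMSE", "CSF_FRACTION",
                                        "WM_FRACTION", "PSEUDO_T1",
                                        "CORRELATION_R", "PVALUE"),
                       voxel_size = c(1, 1, 1), affine = diag(4)) {
  role <- match.arg(role)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  ok <- values[is.finite(values)]
  if (role == "FA" && length(ok) && (min(ok) < -1e-12 || max(ok) > 1 + 1e-9))
    stop("FA values must lie in [0, 1]")
  if (role %in% c("CSF_FRACTION", "WM_FRACTION") && length(ok) &&
      (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
    stop("fractions must lie in [0, 1]")
  if (role == "NRMSE" && length(ok) && min(ok) < -1e-12)
    stop("nRMSE must be nonnegative")
  structure(list(values = values, role = role,
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 affine = affine),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("Scalar map [", x$role, "]: ",
      paste(dim(x$values), collapse = " x "), " grid, range ",
      format(min(v)), " .. ", format(max(v)), "\n", sep = "")
  invisible(x)
}

#' Read/write scalar maps as 3D NIfTI
#'
#' @param file NIfTI path.
#' @param role Role tag to attach on read (see [scalar_map]).
#' @return [scalar_map] (read) or `NULL` invisibly (write).
#' @export
read_scalar_map <- function(file, role = "MPSI") {
  img <- RNifti::readNifti(file)
  scalar_map(array(as.numeric(img), dim = dim(img)[1:3]), role = role,
             voxel_size = RNifti::pixdim(img)[1:3],
             affine = RNifti::xform(img))
}

#' @rdname read_scalar_map
#' @param map A [scalar_map] (or logical 3D array for masks).
#' @export
write_scalar_map <- function(map, file) {
  if (is.logical(map) || !inherits(map, "scalar_map")) {
    img <- RNifti::asNifti(array(as.integer(map), dim = dim(map)))
  } else {
    img <- RNifti::asNifti(map$values)
    RNifti::pixdim(img) <- c(map$voxel_size, 1)[1:3]
  }
  RNifti::writeNifti(img, file)
  invisible(NULL)
}

#' Extract the 3D value array from a scalar map (or pass arrays through)
#'
#' @param x A [scalar_map] or 3D array.
#' @return 3D numeric array.
#' @export
map_values <- function(x) {
  if (inherits(x, "scalar_map")) x$values else as.array(x)
}

#' Per-voxel symmetric pseudo-diffusion tensor field
#'
#' Stores the six unique elements of the symmetric 3 x 3 tensor per voxel
#' (order xx, yy, zz, xy, xz, yz), so symmetry holds exactly by storage. The
#' same container represents the pseudo-diffusion tensor, the molecular
#' diffusion tensor and the velocity-covariance matrix. Eigenvalues are kept
#' as fitted (no clamping); `nonphysical` flags voxels with any negative
#' eigenvalue.
#'
#' @param tensor 4D array (X x Y x Z x 6), mm^2/s.
#' @param s0 3D array of fitted reference signals.
#' @param fit_mask Logical 3D array: voxels that were fit.
#' @param floored Logical 3D array: voxels where nonpositive signals were
#'   floored before the log transform.
#' @param voxel_size,affine Grid geometry.
#' @return Object of class `tensor_field`.
#' @export
tensor_field <- function(tensor, s0 = NULL, fit_mask = NULL, floored = NULL,
                         voxel_size = c(1, 1, 1), affine = diag(4)) {
  tensor <- as.array(tensor)
  d <- dim(tensor)
  if (length(d) != 4L || d[4] != 6L)
    stop("tensor must be X x Y x Z x 6")
  dims <- d[1:3]
  if (is.null(s0)) s0 <- array(1, dims)
  if (is.null(fit_mask)) fit_mask <- array(TRUE, dims)
  if (is.null(floored)) floored <- array(FALSE, dims)
  structure(list(tensor = tensor, s0 = s0, fit_mask = fit_mask,
                 floored = floored, nonphysical = NULL,
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 affine = affine),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("Tensor field:", paste(dim(x$tensor)[1:3], collapse = " x "),
      "grid;", sum(x$fit_mask), "voxels fit\n")
  invisible(x)
}

#' Build an isotropic tensor field d * I from a scalar diffusivity map
#'
#' @param d_map 3D array or [scalar_map] of diffusivities (mm^2/s).
#' @param voxel_size,affine Grid geometry.
#' @return A [tensor_field].
#' @export
isotropic_tensor_field <- function(d_map, voxel_size = c(1, 1, 1),
                                   affine = diag(4)) {
  d <- map_values(d_map)
  dims <- dim(d)
  tens <- array(0, c(dims, 6))
  tens[, , , 1] <- d
  tens[, , , 2] <- d
  tens[, , , 3] <- d
  tensor_field(tens, voxel_size = voxel_size, affine = affine)
}

# internal: tensor field -> D x 6 matrix of unique elements
tensor_mat <- function(field) {
  matrix(field$tensor, ncol = 6L)
}
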