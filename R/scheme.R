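#' Diffusion acquisition scheme
#'
#' Bundles b-values (s/mm^2) and unit gradient directions. By convention the
#' direction stored for a b = 0 entry is the zero vector.
#'
#' @param bvals Numeric vector of b-values, s/mm^2, all >= 0.
#' @param bvecs Gradient directions as a 3 x M matrix (FSL convention) or an
#'   M x 3 matrix; each b > 0 direction must have unit norm (tolerance 1e-6).
#' @return An object of class `acquisition_scheme` with elements `bvals`
#'   (length M) and `bvecs` (M x 3, rows are directions).
#' @examples
#' sch <- acquisition_scheme(c(0, 100), rbind(c(0, 0, 0), c(1, 0, 0)))
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) == 3L && length(bvals) == 3L) {
    # ambiguous 3x3: assume rows are directions (M x 3)
  }
  if (ncol(bvecs) != 3L || nrow(bvecs) != length(bvals))
    stop("bvecs must provide one 3-vector per b-value")
  if (any(bvals < 0)) stop("negative b-value")
  nrm <- sqrt(rowSums(bvecs^2))
  dwi <- bvals > 0
  if (any(abs(nrm[dwi] - 1) > 1e-6))
    stop("non-unit gradient direction for b > 0 entry")
  bvecs[!dwi, ] <- 0
  if (!any(bvals == min(bvals)))
    stop("scheme needs at least one reference (minimum-b) entry")
  structure(list(bvals = bvals, bvecs = bvecs),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat("Acquisition scheme:", length(x$bvals), "volumes;",
      sum(x$bvals == 0), "b=0;",
      "b range", paste(range(x$bvals), collapse = "-"), "s/mm^2\n")
  invisible(x)
}

#' Default multi-low-b acquisition scheme
#'
#' One b = 0 reference plus seven diffusion-weighted volumes with b-values
#' spanning 50-350 s/mm^2 along seven distinct unit directions, emulating a
#' multi-low-b protocol. Suitable for the 7-parameter tensor fit.
#'
#' @return An [acquisition_scheme].
#' @export
default_scheme <- function() {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                c(0, 1, 1) / sqrt(2), c(1, 1, 1) / sqrt(3))
  acquisition_scheme(c(0, seq(50, 350, by = 50)), rbind(c(0, 0, 0), dirs))
}

#' Read an FSL-style bval/bvec pair
#'
#' @param bval_file,bvec_file Paths to whitespace-separated text files; bvals
#'   as one row of M values, bvecs as 3 rows of M columns.
#' @return An [acquisition_scheme].
#' @export
read_scheme <- function(bval_file, bvec_file) {
  bvals <- scan(bval_file, quiet = TRUE)
  bvecs <- matrix(scan(bvec_file, quiet = TRUE), nrow = 3, byrow = TRUE)
  acquisition_scheme(bvals, bvecs)
}

#' Write an FSL-style bval/bvec pair
#'
#' @param scheme An [acquisition_scheme].
#' @param bval_file,bvec_file Output paths.
#' @export
write_scheme <- function(scheme, bval_file, bvec_file) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_file)
  writeLines(apply(t(scheme$bvecs), 1L, paste, collapse = " "), bvec_file)
  invisible(NULL)
}

#' 4D diffusion-weighted image stack
#'
#' @param signal 4D nonnegative array (X x Y x Z x M).
#' @param scheme [acquisition_scheme] with M entries.
#' @param voxel_size Voxel edge lengths in mm (length 3, recycled from 1).
#' @param affine 4 x 4 grid-to-world transform.
#' @return An object of class `dwi_stack`.
#' @export
dwi_stack <- function(signal, scheme, voxel_size = c(1, 1, 1),
                      affine = diag(4)) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array")
  if (dim(signal)[4] != length(scheme$bvals))
    stop("signal volume count does not match scheme length")
  if (any(signal < 0)) stop("signal must be nonnegative")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = voxel_size, affine = affine),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI stack:", paste(d[1:3], collapse = " x "), "grid,",
      d[4], "volumes, voxel", paste(x$voxel_size, collapse = "x"), "mm\n")
  invisible(x)
}

#' Read a 4D NIfTI plus bval/bvec into a DWI stack
#'
#' @param nii_file 4D NIfTI path.
#' @param bval_file,bvec_file FSL-style gradient table paths.
#' @return A [dwi_stack] preserving the NIfTI affine.
#' @export
read_dwi <- function(nii_file, bval_file, bvec_file) {
  img <- RNifti::readNifti(nii_file)
  sch <- read_scheme(bval_file, bvec_file)
  dwi_stack(array(as.numeric(img), dim = dim(img)), sch,
            voxel_size = RNifti::pixdim(img)[1:3],
            affine = RNifti::xform(img))
}

#' Write a DWI stack as 4D NIfTI plus bval/bvec
#'
#' @param dwi A [dwi_stack].
#' @param nii_file,bval_file,bvec_file Output paths.
#' @export
write_dwi <- function(dwi, nii_file, bval_file, bvec_file) {
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, nii_file)
  write_scheme(dwi$scheme, bval_file, bvec_file)
  invisible(NULL)
}
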