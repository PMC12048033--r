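# Synthetic low-b DWI phantom populations with planted ground truth.
#
# The generator plants K spatial patterns (CSF "waterway" stand-ins) with
# per-subject coefficients driven by covariates, embeds them in a
# CSF/parenchyma diffusivity contrast, synthesizes DWI volumes through the
# monoexponential pseudo-diffusion forward model, and corrupts them with
# Rician noise. Every downstream stage (tensor fit, masking, NMF, stability
# selection, cohort statistics) can therefore be tested against known truth.

#' Phantom population configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 20 x 20 x 20 grid with 4 disjoint block patterns, 40 subjects and
#' low Rician noise.
#'
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param voxel_size mm per axis.
#' @param n_subjects Number of subjects.
#' @param k_true Number of planted spatial patterns (>= 1).
#' @param pattern_geometry `"blocks"` (disjoint axis-aligned blocks),
#'   `"blobs"` (Gaussian blobs at seeded random centres) or
#'   `"mirrored_blobs"` (blobs mirrored across the x midline, emulating
#'   bilateral symmetry).
#' @param coeff_effects Named list mapping covariate name (`age`, `sex`,
#'   `bpf`, `vv`, `cbf`) to a standardized effect size per pattern (a single
#'   beta applied to every pattern, or a length-`k_true` vector).
#' @param noise_sigma Rician noise scale relative to `s0` (>= 0).
#' @param base_mpsi CSF-level mean pseudo-diffusivity scale, mm^2/s.
#' @param csf_contrast List with `csf = c(md, fa)` and `parenchyma = c(md,
#'   fa)` class means (mm^2/s, unitless) setting the two-tissue diffusion
#'   contrast.
#' @param coeff_cv Coefficient of variation of the pattern coefficients
#'   across subjects (the planted covariate-plus-noise score is standardized
#'   and enters multiplicatively at this scale).
#' @param outlier_spec Optional `list(n_outliers, z_offset, patterns)`:
#'   subjects whose coefficients on `patterns` are shifted by `z_offset`
#'   standard deviations.
#' @param anisotropic If `TRUE`, parenchyma voxels get axis-aligned prolate
#'   tensors with the configured FA; default is isotropic Psi = MPsi * I
#'   everywhere.
#' @param n_cohorts Number of cohorts (subjects assigned round-robin).
#' @param cohort_offsets Per-cohort shift of the latent coefficient score, in
#'   score SD units (length `n_cohorts`).
#' @param s0 Reference signal level.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(20, 20, 20),
                           voxel_size = c(2, 2, 2),
                           n_subjects = 40,
                           k_true = 4,
                           pattern_geometry = c("blocks", "blobs",
                                                "mirrored_blobs"),
                           coeff_effects = list(),
                           noise_sigma = 0.02,
                           base_mpsi = 3e-3,
                           csf_contrast = list(csf = c(md = 3e-3, fa = 0.05),
                                               parenchyma = c(md = 0.8e-3,
                                                              fa = 0.4)),
                           coeff_cv = 0.2,
                           outlier_spec = NULL,
                           anisotropic = FALSE,
                           n_cohorts = 1,
                           cohort_offsets = rep(0, n_cohorts),
                           s0 = 100,
                           seed = 1L) {
  pattern_geometry <- match.arg(pattern_geometry)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            n_subjects >= 1, k_true >= 1, noise_sigma >= 0,
            base_mpsi > 0, coeff_cv >= 0,
            length(cohort_offsets) == n_cohorts)
  if (!is.null(outlier_spec)) {
    outlier_spec <- utils::modifyList(list(n_outliers = 1, z_offset = 4,
                                           patterns = 1L), outlier_spec)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = rep_len(as.numeric(voxel_size), 3L),
                 n_subjects = as.integer(n_subjects),
                 k_true = as.integer(k_true),
                 pattern_geometry = pattern_geometry,
                 coeff_effects = coeff_effects,
                 noise_sigma = noise_sigma, base_mpsi = base_mpsi,
                 csf_contrast = csf_contrast, coeff_cv = coeff_cv,
                 outlier_spec = outlier_spec, anisotropic = anisotropic,
                 n_cohorts = as.integer(n_cohorts),
                 cohort_offsets = cohort_offsets,
                 s0 = s0, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Axis-aligned prolate tensor with given mean diffusivity and FA
#'
#' Returns the six unique elements (xx, yy, zz, xy, xz, yz) of
#' diag(l1, l2, l2) with (l1 + 2 l2)/3 = `md` and the requested fractional
#' anisotropy; the long axis is x. Closed-form, used to give phantoms exact
#' FA targets.
#'
#' @param md Mean diffusivity, mm^2/s.
#' @param fa Fractional anisotropy in \[0, 1).
#' @return Numeric length-6 vector.
#' @export
prolate_tensor <- function(md, fa) {
  stopifnot(md >= 0, fa >= 0, fa < 1)
  if (fa == 0) return(c(md, md, md, 0, 0, 0))
  # solve lambda1/lambda2 = r from FA = (r - 1) / sqrt(r^2 + 2)
  f2 <- fa^2
  r <- (1 + sqrt(1 - (1 - f2) * (1 - 2 * f2))) / (1 - f2)
  l2 <- 3 * md / (r + 2)
  c(r * l2, l2, l2, 0, 0, 0)
}

# ---- pattern geometry ------------------------------------------------------

# disjoint axis-aligned blocks on a cell lattice, 1-voxel margins
pattern_blocks <- function(grid, k) {
  nx <- ceiling(k^(1 / 3))
  ny <- ceiling(sqrt(k / nx))
  nz <- ceiling(k / (nx * ny))
  cells <- c(nx, ny, nz)
  cell_dim <- floor(grid / cells)
  if (any(cell_dim < 3))
    stop("degenerate geometry: grid too small to host ", k,
         " disjoint blocks with margins")
  W <- matrix(0, prod(grid), k)
  kk <- 0L
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (kk >= k) break
    kk <- kk + 1L
    lo <- (c(ix, iy, iz) - 1L) * cell_dim + 2L
    hi <- c(ix, iy, iz) * cell_dim - 1L
    m <- array(FALSE, grid)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    W[as.vector(m), kk] <- 1
  }
  W
}

pattern_blobs <- function(grid, k, mirrored = FALSE) {
  co <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                              z = seq_len(grid[3])))
  sigma <- max(2, min(grid) / 8)
  n_free <- if (mirrored) ceiling(k / 2) else k
  centres <- cbind(stats::runif(n_free, 1 + sigma, grid[1] - sigma),
                   stats::runif(n_free, 1 + sigma, grid[2] - sigma),
                   stats::runif(n_free, 1 + sigma, grid[3] - sigma))
  if (mirrored) {
    mir <- centres
    mir[, 1] <- grid[1] + 1 - mir[, 1]
    centres <- rbind(centres, mir)[seq_len(k), , drop = FALSE]
  }
  W <- sapply(seq_len(k), function(j) {
    d2 <- (co[, 1] - centres[j, 1])^2 + (co[, 2] - centres[j, 2])^2 +
      (co[, 3] - centres[j, 3])^2
    v <- exp(-d2 / (2 * sigma^2))
    v[v < 0.05] <- 0
    v
  })
  W
}

# ---- forward signal model --------------------------------------------------

#' Synthesize DWI volumes from a tensor field
#'
#' Monoexponential forward model S = s0 * exp(-b g' Psi g), with optional
#' Rician corruption (magnitude of a complex Gaussian perturbation with per
#' channel SD `noise_sigma * s0`) or plain additive Gaussian noise. An
#' optional per-volume multiplicative jitter of the tensor (`pulsatility`)
#' emulates ungated cardiac/respiratory variation of CSF flow.
#'
#' @param psi A [tensor_field] (per-voxel Psi, mm^2/s).
#' @param scheme An [acquisition_scheme].
#' @param s0 Reference signal (positive scalar).
#' @param noise_sigma Noise scale relative to `s0` (>= 0).
#' @param seed Integer seed for the noise draws.
#' @param noise_model `"rician"` (default, magnitude MRI) or `"gaussian"`.
#' @param pulsatility SD of the per-volume relative tensor jitter (default 0).
#' @return A [dwi_stack].
#' @examples
#' tf <- isotropic_tensor_field(array(3e-3, c(2, 2, 2)))
#' dwi <- forward_signal(tf, default_scheme(), s0 = 1, noise_sigma = 0)
#' @export
forward_signal <- function(psi, scheme, s0 = 100, noise_sigma = 0,
                           seed = 0L, noise_model = c("rician", "gaussian"),
                           pulsatility = 0) {
  stopifnot(inherits(psi, "tensor_field"),
            inherits(scheme, "acquisition_scheme"), s0 > 0)
  noise_model <- match.arg(noise_model)
  if (any(scheme$bvals < 0)) stop("negative b-value")
  nrm <- sqrt(rowSums(scheme$bvecs^2))
  if (any(abs(nrm[scheme$bvals > 0] - 1) > 1e-6))
    stop("non-unit gradient direction")
  dims <- dim(psi$tensor)[1:3]
  nvox <- prod(dims)
  m <- tensor_mat(psi)
  g <- scheme$bvecs
  qf <- outer(g[, 1]^2, m[, 1]) + outer(g[, 2]^2, m[, 2]) +
    outer(g[, 3]^2, m[, 3]) + 2 * outer(g[, 1] * g[, 2], m[, 4]) +
    2 * outer(g[, 1] * g[, 3], m[, 5]) + 2 * outer(g[, 2] * g[, 3], m[, 6])
  set.seed(seed)
  batt <- scheme$bvals
  if (pulsatility > 0)
    batt <- batt * (1 + stats::rnorm(length(batt), 0, pulsatility))
  S <- s0 * exp(-batt * qf)                    # volumes x voxels
  if (noise_sigma > 0) {
    sd <- noise_sigma * s0
    if (noise_model == "rician") {
      e1 <- matrix(stats::rnorm(length(S), 0, sd), nrow(S))
      e2 <- matrix(stats::rnorm(length(S), 0, sd), nrow(S))
      S <- sqrt((S + e1)^2 + e2^2)
    } else {
      S <- pmax(S + matrix(stats::rnorm(length(S), 0, sd), nrow(S)), 0)
    }
  }
  sig <- array(t(S), c(dims, length(scheme$bvals)))
  dwi_stack(sig, scheme, voxel_size = psi$voxel_size, affine = psi$affine)
}

# ---- population generator --------------------------------------------------

#' Generate a phantom low-b DWI population with known ground truth
#'
#' Plants `k_true` nonnegative spatial patterns `W_true`, draws per-subject
#' coefficients `H_true` whose variation follows the configured covariate
#' effects (the latent score has unit total variance, so a stated effect size
#' is the true standardized regression coefficient), embeds the resulting
#' mean-pseudo-diffusivity fields in a parenchyma background, and synthesizes
#' each subject's DWI stack through [forward_signal].
#'
#' @param config A [phantom_config].
#' @param scheme [acquisition_scheme] used for every subject; default
#'   [default_scheme()].
#' @return A list with elements
#'   \describe{
#'     \item{dwi}{list of per-subject [dwi_stack]s}
#'     \item{truth}{`phantom_truth`: `W_true` (voxels x K), `H_true`
#'       (K x N), `labels_true` (3D integer array, 0 = background),
#'       `csf_mask` (3D logical), `mpsi_true` (list of 3D arrays),
#'       `psi_true` (list of [tensor_field]s), `outliers` (subject indices),
#'       `config`}
#'     \item{subjects}{covariate data.frame: `subject_id`, `cohort`, `age`,
#'       `sex`, `bpf`, `vv`, `cbf`}
#'   }
#' @export
make_phantom_population <- function(config, scheme = default_scheme()) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid_shape
  k <- config$k_true
  n <- config$n_subjects
  if (k > prod(grid)) stop("more patterns than voxels")
  set.seed(config$seed)

  W <- switch(config$pattern_geometry,
              blocks = pattern_blocks(grid, k),
              blobs = pattern_blobs(grid, k),
              mirrored_blobs = pattern_blobs(grid, k, mirrored = TRUE))
  support <- rowSums(W) > 0
  labels <- integer(prod(grid))
  labels[support] <- max.col(W[support, , drop = FALSE], ties.method = "first")
  labels_true <- array(labels, grid)
  csf_mask <- array(support, grid)

  subjects <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    cohort = paste0("cohort", rep_len(seq_len(config$n_cohorts), n)),
    age = stats::runif(n, 45, 90),
    sex = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE)
  subjects$bpf <- pmin(pmax(0.82 - 0.0025 * (subjects$age - 45) +
                              stats::rnorm(n, 0, 0.05), 0.5), 0.95)
  subjects$vv <- pmax(0.01 + 4e-4 * (subjects$age - 45) +
                        stats::rnorm(n, 0, 0.005), 1e-3)
  subjects$cbf <- 55 - 0.2 * (subjects$age - 45) + stats::rnorm(n, 0, 5)

  covz <- scale(cbind(age = subjects$age, sex = subjects$sex,
                      bpf = subjects$bpf, vv = subjects$vv,
                      cbf = subjects$cbf))
  covz[!is.finite(covz)] <- 0   # constant covariate at small N
  eff <- config$coeff_effects
  betas <- matrix(0, k, ncol(covz), dimnames = list(NULL, colnames(covz)))
  for (nm in names(eff)) {
    if (!nm %in% colnames(covz)) stop("unknown covariate in coeff_effects: ", nm)
    betas[, nm] <- rep_len(eff[[nm]], k)
  }
  H <- matrix(0, k, n)
  for (j in seq_len(k)) {
    b <- betas[j, ]
    ss <- sum(b^2)
    if (ss > 1) stop("sum of squared effect sizes exceeds 1 for pattern ", j)
    score <- as.vector(covz %*% b) +
      sqrt(1 - ss) * stats::rnorm(n)           # unit total variance
    score <- score + config$cohort_offsets[
      rep_len(seq_len(config$n_cohorts), n)]
    H[j, ] <- pmax(1 + config$coeff_cv * score, 0.05)
  }
  outliers <- integer(0)
  if (!is.null(config$outlier_spec)) {
    os <- config$outlier_spec
    outliers <- sort(sample.int(n, os$n_outliers))
    for (j in os$patterns) {
      H[j, outliers] <- H[j, outliers] + os$z_offset * stats::sd(H[j, ])
    }
  }

  par_md <- config$csf_contrast$parenchyma[["md"]]
  par_fa <- if (config$anisotropic) config$csf_contrast$parenchyma[["fa"]] else 0
  par_tensor <- prolate_tensor(par_md, par_fa)

  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  dwi <- vector("list", n)
  mpsi_true <- vector("list", n)
  psi_true <- vector("list", n)
  for (i in seq_len(n)) {
    mpsi <- config$base_mpsi * as.vector(W %*% H[, i])
    mpsi[!support] <- par_md
    mpsi_true[[i]] <- array(mpsi, grid)
    tens <- array(0, c(grid, 6))
    tm <- matrix(tens, ncol = 6L)
    tm[support, 1:3] <- mpsi[support]
    tm[!support, ] <- matrix(par_tensor, sum(!support), 6, byrow = TRUE)
    psi_true[[i]] <- tensor_field(array(tm, c(grid, 6)),
                                  voxel_size = config$voxel_size)
    dwi[[i]] <- forward_signal(psi_true[[i]], scheme, s0 = config$s0,
                               noise_sigma = config$noise_sigma,
                               seed = sub_seeds[i])
  }
  truth <- structure(list(W_true = W, H_true = H, labels_true = labels_true,
                          csf_mask = csf_mask, mpsi_true = mpsi_true,
                          psi_true = psi_true, outliers = outliers,
                          config = config),
                     class = "phantom_truth")
  list(dwi = dwi, truth = truth, subjects = subjects)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("Phantom truth:", ncol(x$W_true), "patterns,",
      ncol(x$H_true), "subjects,",
      sum(x$csf_mask), "pattern-support voxels\n")
  invisible(x)
}

#' Write a phantom population to disk
#'
#' DWI as 4D NIfTI with FSL-style bval/bvec, covariates as TSV, and the truth
#' bundle as plain-text arrays with a JSON sidecar.
#'
#' @param pop Result of [make_phantom_population].
#' @param dir Output directory (created if missing).
#' @export
write_phantom_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pop$dwi)) {
    stub <- file.path(dir, pop$subjects$subject_id[i])
    write_dwi(pop$dwi[[i]], paste0(stub, "_dwi.nii.gz"),
              paste0(stub, ".bval"), paste0(stub, ".bvec"))
  }
  utils::write.table(pop$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(pop$truth$W_true, file.path(dir, "W_true.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(pop$truth$H_true, file.path(dir, "H_true.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  cfg <- pop$truth$config
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    json <- jsonlite::toJSON(cfg[!vapply(cfg, is.list, TRUE)],
                             auto_unbox = TRUE, digits = NA)
    writeLines(json, file.path(dir, "truth.json"))
  }
  invisible(dir)
}
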