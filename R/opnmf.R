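# Orthonormal projective non-negative matrix factorization (opNMF).
#
# Decomposes the nonnegative voxels x subjects data matrix X ~ W H with
# W >= 0, approximately orthonormal columns (W'W = I) and projective
# coefficients H = W'X, so each column of W is an interpretable spatial
# covariation pattern and voxels are effectively parcellated by their
# dominant pattern. Fitting is by the projective multiplicative update
#   W <- W * (X X' W) / (W W' X X' W),
# with entries floored at 1e-16 and W rescaled by its spectral norm each
# iteration; columns are l2-normalized on output. (Per-iteration column
# normalization was tried and rejected: it creates stable non-orthonormal
# fixed points where one pattern stays global, whereas the scalar rescaling
# leaves relative column scales free and the update then drives the basis
# to the parts-based, near-orthonormal solution.) The objective is the
# Frobenius reconstruction error ||X - W W' X||_F of the column-normalized
# iterate. All products with X X' are computed as X (X' W) so the D x D
# Gram matrix is never formed.

#' Assemble the voxels-by-subjects data matrix from a map stack
#'
#' Rows follow the mask scan order of R arrays (x fastest).
#'
#' @param mpsi_stack List of per-subject [scalar_map]s (or 3D arrays).
#' @param mask Logical 3D array selecting the CSF analysis domain.
#' @param subject_ids Optional column labels.
#' @return Object of class `data_matrix`: nonnegative matrix `X` (D x N),
#'   integer vector `voxel_index` (linear indices into the grid), `dims`.
#' @export
build_data_matrix <- function(mpsi_stack, mask, subject_ids = NULL) {
  X <- stack_matrix(mpsi_stack)[which(mask), , drop = FALSE]
  if (any(is.na(X))) stop("NA values inside the mask")
  if (any(X < 0)) stop("data matrix must be nonnegative")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(ncol(X)))
  colnames(X) <- subject_ids
  structure(list(X = X, voxel_index = which(mask), dims = dim(mask)),
            class = "data_matrix")
}

as_X <- function(X) {
  if (inherits(X, "data_matrix")) X$X else as.matrix(X)
}

# nonnegative double SVD initialization (deterministic); exact zeros filled
# with a small positive value so the multiplicative update cannot lock them
nndsvd_init <- function(X, K) {
  sv <- svd(X, nu = K, nv = K)
  W0 <- matrix(0, nrow(X), K)
  W0[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  if (K > 1) for (j in 2:K) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    # keep the sign-split direction even when the singular value is ~0
    # (columns are renormalized below); distinct directions prevent the
    # multiplicative update from locking collinear columns together
    W0[, j] <- if (npos >= nneg && sum(up^2) > 0) {
      up / sqrt(sum(up^2))
    } else if (sum(un^2) > 0) {
      un / sqrt(sum(un^2))
    } else {
      abs(u) / sqrt(sum(u^2))
    }
    W0[, j] <- sqrt(max(sv$d[j], 1e-6 * sv$d[1])) * W0[, j]
  }
  W0[W0 <= 0] <- 1e-6 * mean(X)
  W0
}

#' Fit orthonormal projective NMF
#'
#' @param X A [build_data_matrix] result or a nonnegative D x N matrix.
#' @param K Number of patterns, `1 <= K <= min(D, N)`.
#' @param init `"nndsvd"` (deterministic nonnegative double SVD, default) or
#'   `"random"` (seeded uniform).
#' @param seed Seed for random initialization.
#' @param max_iter Maximum multiplicative updates (default 50000).
#' @param tol Convergence: relative change of the objective below `tol`
#'   (default 1e-6).
#' @return Object of class `opnmf`: `W` (D x K, nonnegative, approximately
#'   orthonormal columns), `H = W'X` (K x N, recomputed at output),
#'   `recon_error` (Frobenius), `objective` (per-iteration trace), `n_iter`,
#'   `converged`, `K`, plus `voxel_index`/`dims` when `X` is a
#'   [build_data_matrix] result.
#' @examples
#' X <- matrix(rexp(20 * 6), 20, 6)
#' f <- opnmf_fit(X, K = 2)
#' f
#' @export
opnmf_fit <- function(X, K, init = c("nndsvd", "random"), seed = 0L,
                      max_iter = 50000L, tol = 1e-6) {
  init <- match.arg(init)
  dm <- if (inherits(X, "data_matrix")) X else NULL
  X <- as_X(X)
  if (any(X < 0)) stop("X must be nonnegative")
  D <- nrow(X); N <- ncol(X)
  if (K < 1L || K > min(D, N))
    stop("K must lie in [1, min(D, N)] = [1, ", min(D, N), "]")
  eps <- 1e-16
  normX2 <- sum(X^2)

  W <- switch(init,
              nndsvd = nndsvd_init(X, K),
              random = {
                set.seed(seed)
                matrix(stats::runif(D * K, 0.1, 1), D, K)
              })
  W <- sweep(W, 2L, pmax(sqrt(colSums(W^2)), eps), "/")

  objective <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  it <- 0L
  # ||X - W W'X||_F of the iterate via K x K blocks (never forms X X')
  objfun <- function(W) {
    H <- crossprod(W, X)
    sqrt(max(normX2 - 2 * sum(H^2) + sum(crossprod(W) * tcrossprod(H)), 0))
  }
  while (it < max_iter) {
    it <- it + 1L
    XtW <- crossprod(X, W)                 # N x K (= H')
    XXtW <- X %*% XtW                      # D x K
    HHt <- crossprod(XtW)                  # K x K (= W'X X'W)
    ratio <- XXtW / pmax(W %*% HHt, eps)
    step <- 1
    repeat {
      Wc <- W * (if (step == 1) ratio else ratio^step)
      Wc[Wc < eps] <- eps
      G <- crossprod(Wc)
      Wc <- Wc / sqrt(max(eigen(G, symmetric = TRUE,
                                only.values = TRUE)$values))
      obj <- objfun(Wc)
      # damp the multiplicative step if it would increase the objective
      if (!is.finite(obj_prev) || obj <= obj_prev + 1e-12 || step <= 1 / 64)
        break
      step <- step / 2
    }
    W <- Wc
    objective[it] <- obj
    # stop on small relative change, or when the fit is essentially exact
    # (the objective decays geometrically on noiseless data and would never
    # satisfy a purely relative criterion)
    if (obj <= 1e-9 * sqrt(normX2) ||
        (is.finite(obj_prev) &&
           abs(obj_prev - obj) <= tol * max(obj_prev, eps))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  W <- sweep(W, 2L, pmax(sqrt(colSums(W^2)), eps), "/")
  H <- crossprod(W, X)
  out <- structure(list(W = W, H = H, K = K,
                        recon_error = objfun(W),
                        objective = objective, n_iter = it,
                        converged = converged, init = init,
                        subject_ids = colnames(X),
                        voxel_index = dm$voxel_index, dims = dm$dims),
                   class = "opnmf")
  out
}

#' @export
print.opnmf <- function(x, ...) {
  cat("Orthonormal projective NMF: K =", x$K, "patterns,",
      nrow(x$W), "voxels x", ncol(x$H), "subjects\n")
  cat("  reconstruction error (Frobenius):", format(x$recon_error), "\n")
  cat("  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  max |W'W - I|:", format(max(abs(crossprod(x$W) - diag(x$K)))), "\n")
  invisible(x)
}

#' @export
summary.opnmf <- function(object, ...) {
  lab <- hard_labels(object$W)
  sizes <- tabulate(lab$labels, nbins = object$K)
  out <- list(K = object$K, recon_error = object$recon_error,
              n_iter = object$n_iter, converged = object$converged,
              orthonormality = max(abs(crossprod(object$W) -
                                         diag(object$K))),
              pattern_sizes = sizes,
              coefficient_means = rowMeans(object$H))
  class(out) <- "summary.opnmf"
  out
}

#' @export
print.summary.opnmf <- function(x, ...) {
  cat("opNMF summary: K =", x$K, "\n")
  cat("  reconstruction error:", format(x$recon_error), "\n")
  cat("  ||W'W - I||_max:", format(x$orthonormality), "\n")
  cat("  pattern sizes (voxels):", paste(x$pattern_sizes, collapse = ", "),
      "\n")
  cat("  mean coefficients:",
      paste(signif(x$coefficient_means, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.opnmf <- function(object, ...) object$H

#' @export
fitted.opnmf <- function(object, ...) object$W %*% object$H

#' Project new subjects onto a fitted basis
#'
#' @param object Fitted `opnmf`.
#' @param newdata D x M nonnegative matrix (same voxel rows as the training
#'   X); when omitted, returns the fitted reconstruction.
#' @param ... Unused.
#' @return Projective coefficients `W' newdata` (K x M), or `W H`.
#' @export
predict.opnmf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  crossprod(object$W, as_X(newdata))
}

#' @export
plot.opnmf <- function(x, ...) {
  graphics::plot(seq_along(x$objective), x$objective, type = "l",
                 xlab = "iteration", ylab = "||X - WW'X||_F",
                 main = paste0("opNMF objective (K = ", x$K, ")"), ...)
  invisible(x)
}

#' Frobenius reconstruction error of a projective basis
#'
#' `||X - W (W'X)||_F`, the criterion used to compare solutions across K.
#'
#' @param X Data matrix (or [build_data_matrix] result).
#' @param W D x K basis.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(X, W) {
  X <- as_X(X)
  W <- as.matrix(W)
  sqrt(sum((X - W %*% crossprod(W, X))^2))
}

#' Hard pattern labels from a basis (the waterway atlas)
#'
#' Assigns each voxel to the pattern with the largest basis weight; ties are
#' broken toward the lowest column index and flagged. All-zero rows get label
#' 1 with the tie flag set.
#'
#' @param W D x K nonnegative basis (or a fitted `opnmf`).
#' @return List of class `label_map`: `labels` (integer vector in 1..K),
#'   `tie_flag` (logical), `K`, and (when available from the fit)
#'   `voxel_index`/`dims` to place labels on the grid via [label_array].
#' @export
hard_labels <- function(W) {
  fit <- NULL
  if (inherits(W, "opnmf")) { fit <- W; W <- W$W }
  W <- as.matrix(W)
  if (ncol(W) < 1L) stop("W needs at least one column")
  lab <- max.col(W, ties.method = "first")
  mx <- W[cbind(seq_len(nrow(W)), lab)]
  tie <- rowSums(W == mx) > 1L
  structure(list(labels = lab, tie_flag = tie, K = ncol(W),
                 voxel_index = fit$voxel_index, dims = fit$dims),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("Label map:", length(x$labels), "voxels,", x$K, "patterns;",
      sum(x$tie_flag), "ties\n")
  invisible(x)
}

#' Place a label map on its 3D grid
#'
#' @param lab A `label_map` carrying `voxel_index` and `dims`, or a label
#'   vector with `mask`.
#' @param mask Logical 3D array (needed when `lab` lacks grid info).
#' @return Integer 3D array; 0 outside the mask.
#' @export
label_array <- function(lab, mask = NULL) {
  if (inherits(lab, "label_map") && !is.null(lab$dims)) {
    out <- array(0L, lab$dims)
    out[lab$voxel_index] <- lab$labels
    return(out)
  }
  stopifnot(!is.null(mask))
  out <- array(0L, dim(mask))
  labels <- if (inherits(lab, "label_map")) lab$labels else as.integer(lab)
  out[which(mask)] <- labels
  out
}
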