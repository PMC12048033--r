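# Model-order selection for the opNMF parcellation: covariate-balanced split
# halves, bootstrap resampling, adjusted Rand index between half-specific
# parcellations, and selection of K by reproducibility (highest mean ARI)
# and reliability (lowest ARI standard deviation).

#' Covariate-balanced split into two halves
#'
#' Splits subjects into halves whose sizes differ by at most one, minimizing
#' the summed absolute standardized difference in covariate means between the
#' halves (binary covariates are compared as proportions). Anticlustering is
#' approximated with a greedy pairwise-exchange heuristic from a seeded
#' random start, so the split is deterministic given the seed.
#'
#' @param covariates Data frame of subject covariates.
#' @param balance_on Character vector of column names to balance.
#' @param seed Integer seed.
#' @return List `a`, `b` of row indices, plus `objective` (the achieved
#'   imbalance).
#' @export
balanced_split <- function(covariates, balance_on = c("age", "sex"),
                           seed = 0L) {
  n <- nrow(covariates)
  if (n < 4L) stop("need at least 4 subjects to split")
  missing_cov <- setdiff(balance_on, names(covariates))
  if (length(missing_cov))
    stop("covariates not found: ", paste(missing_cov, collapse = ", "))
  Z <- sapply(balance_on, function(nm) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    s <- stats::sd(v)
    if (s == 0) rep(0, n) else (v - mean(v)) / s
  })
  Z <- matrix(Z, nrow = n)
  na <- ceiling(n / 2)
  set.seed(seed)
  in_a <- logical(n)
  in_a[sample.int(n, na)] <- TRUE

  obj <- function(in_a) {
    sum(abs(colMeans(Z[in_a, , drop = FALSE]) -
              colMeans(Z[!in_a, , drop = FALSE])))
  }
  cur <- obj(in_a)
  repeat {
    best <- cur; swap <- NULL
    ia <- which(in_a); ib <- which(!in_a)
    for (i in ia) for (j in ib) {
      cand <- in_a
      cand[i] <- FALSE; cand[j] <- TRUE
      o <- obj(cand)
      if (o < best - 1e-12) { best <- o; swap <- c(i, j) }
    }
    if (is.null(swap)) break
    in_a[swap[1]] <- FALSE; in_a[swap[2]] <- TRUE
    cur <- best
  }
  list(a = which(in_a), b = which(!in_a), objective = cur)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: (Index - Expected) /
#' (Max - Expected) from the contingency table. 1 means a perfect match
#' (up to relabelling); values near 0 indicate chance-level agreement. Two
#' identical single-cluster partitions return 1 (the 0/0 case).
#'
#' @param labels_a,labels_b Integer (or factor) label vectors of equal
#'   length >= 2.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 elements")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (mx - expected)
}

#' Split-half bootstrap stability sweep over K
#'
#' For each bootstrap replicate: draw a covariate-balanced split (a fresh
#' split per replicate by default), resample each half's subjects with
#' replacement, fit opNMF on each half's submatrix for every K in `k_range`,
#' and compute the ARI between the two halves' hard voxel label maps.
#' Reports the per-K mean and SD of ARI across replicates plus the full-data
#' reconstruction error, and selects K by highest mean ARI (reproducibility)
#' and lowest ARI SD (reliability); when the two disagree, the final choice
#' is the one with the lower reconstruction error.
#'
#' @param X [build_data_matrix] result or nonnegative D x N matrix.
#' @param covariates Data frame with one row per subject (column order must
#'   match the columns of `X`).
#' @param k_range Candidate pattern counts, default `2:25`.
#' @param n_boot Number of split-half bootstraps, default 20.
#' @param balance_on Covariates to balance the splits on.
#' @param seed Integer seed.
#' @param fixed_split If `TRUE`, reuse one balanced split across bootstraps
#'   (only the resampling varies).
#' @param init,max_iter,tol Passed to [opnmf_fit].
#' @return Object of class `stability_sweep`: data.frame `sweep` (`K`,
#'   `mean_ari`, `sd_ari`, `recon_error`), `ari` (n_boot x K matrix),
#'   `k_best_ari`, `k_best_sd`, `k_selected`, `n_boot`, `seed`.
#' @export
stability_sweep <- function(X, covariates, k_range = 2:25, n_boot = 20L,
                            balance_on = c("age", "sex"), seed = 0L,
                            fixed_split = FALSE, init = "nndsvd",
                            max_iter = 5000L, tol = 1e-5) {
  Xm <- as_X(X)
  n <- ncol(Xm)
  if (n < 8L) stop("need at least 8 subjects")
  if (nrow(covariates) != n)
    stop("covariate rows do not match subjects")
  if (max(k_range) > min(nrow(Xm), floor(n / 2)))
    stop("k_range exceeds min(D, N/2)")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (n_boot == 1L)
    warning("n_boot = 1: ARI standard deviation is undefined, reported as 0")

  ari <- matrix(NA_real_, n_boot, length(k_range),
                dimnames = list(NULL, paste0("K", k_range)))
  for (b in seq_len(n_boot)) {
    sp <- balanced_split(covariates, balance_on,
                         seed = if (fixed_split) seed else seed + b)
    set.seed(seed + 7919L * b)
    ia <- sample(sp$a, length(sp$a), replace = TRUE)
    ib <- sample(sp$b, length(sp$b), replace = TRUE)
    Xa <- Xm[, ia, drop = FALSE]
    Xb <- Xm[, ib, drop = FALSE]
    for (ki in seq_along(k_range)) {
      K <- k_range[ki]
      la <- tryCatch(
        hard_labels(opnmf_fit(Xa, K, init = init, seed = seed + b,
                              max_iter = max_iter, tol = tol))$labels,
        error = function(e) stop("opNMF failed at bootstrap ", b, ", K = ",
                                 K, ": ", conditionMessage(e)))
      lb <- tryCatch(
        hard_labels(opnmf_fit(Xb, K, init = init, seed = seed + b,
                              max_iter = max_iter, tol = tol))$labels,
        error = function(e) stop("opNMF failed at bootstrap ", b, ", K = ",
                                 K, ": ", conditionMessage(e)))
      ari[b, ki] <- adjusted_rand_index(la, lb)
    }
  }
  recon <- vapply(k_range, function(K) {
    opnmf_fit(Xm, K, init = init, seed = seed, max_iter = max_iter,
              tol = tol)$recon_error
  }, numeric(1))

  mean_ari <- colMeans(ari)
  sd_ari <- if (n_boot > 1L) apply(ari, 2L, stats::sd) else rep(0, ncol(ari))
  sweep_df <- data.frame(K = k_range, mean_ari = mean_ari, sd_ari = sd_ari,
                         recon_error = recon, row.names = NULL)
  k_best_ari <- k_range[which.max(mean_ari)]
  k_best_sd <- k_range[which.min(sd_ari)]
  k_selected <- if (k_best_ari == k_best_sd) k_best_ari else {
    cand <- c(k_best_ari, k_best_sd)
    cand[which.min(recon[match(cand, k_range)])]
  }
  structure(list(sweep = sweep_df, ari = ari, k_best_ari = k_best_ari,
                 k_best_sd = k_best_sd, k_selected = k_selected,
                 n_boot = n_boot, seed = seed),
            class = "stability_sweep")
}

#' @export
print.stability_sweep <- function(x, ...) {
  cat("Split-half bootstrap stability sweep (", x$n_boot, " bootstraps)\n",
      sep = "")
  print(transform(x$sweep, mean_ari = signif(mean_ari, 3),
                  sd_ari = signif(sd_ari, 3),
                  recon_error = signif(recon_error, 4)), row.names = FALSE)
  cat("Highest mean ARI at K =", x$k_best_ari,
      "; lowest ARI SD at K =", x$k_best_sd,
      "; selected K =", x$k_selected, "\n")
  invisible(x)
}

#' @export
plot.stability_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  s <- x$sweep
  graphics::plot(s$K, s$mean_ari, type = "b", ylim = c(0, 1),
                 xlab = "K", ylab = "ARI", main = "Split-half stability")
  graphics::arrows(s$K, s$mean_ari - s$sd_ari, s$K, s$mean_ari + s$sd_ari,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(v = x$k_selected, lty = 2)
  graphics::plot(s$K, s$recon_error, type = "b", xlab = "K",
                 ylab = "||X - WW'X||_F", main = "Reconstruction error")
  invisible(x)
}
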