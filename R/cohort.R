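# Cohort-level analyses on the waterway atlas: per-pattern mean
# pseudo-diffusivity tables, IQR outlier exclusion, determinant GLMs and
# mixed models, aberrant-flow detection, and Fisher exact enrichment.

#' Per-subject, per-pattern mean pseudo-diffusivity table
#'
#' Unweighted mean map value over each atlas pattern's voxels, one row per
#' subject, with covariates joined when supplied.
#'
#' @param mpsi_stack List of per-subject [scalar_map]s aligned with the
#'   atlas.
#' @param atlas Integer 3D array of pattern labels (0 = background), or a
#'   `label_map` from [hard_labels].
#' @param covariates Optional data frame (one row per subject) to join.
#' @return Data frame with columns `subject_id`, `cww1` ... `cwwK`, plus the
#'   covariates.
#' @export
cww_means <- function(mpsi_stack, atlas, covariates = NULL) {
  if (inherits(atlas, "label_map")) atlas <- label_array(atlas)
  dims <- dim(map_values(mpsi_stack[[1]]))
  if (!identical(dim(atlas), dims))
    stop("atlas grid does not match the map stack")
  K <- max(atlas)
  if (K < 1L) stop("atlas contains no labelled voxels")
  vox <- lapply(seq_len(K), function(k) which(atlas == k))
  empty <- which(vapply(vox, length, 1L) == 0L)
  if (length(empty))
    stop("empty atlas pattern(s): ", paste(empty, collapse = ", "))
  X <- stack_matrix(mpsi_stack)
  out <- data.frame(subject_id = sprintf("sub-%03d", seq_len(ncol(X))))
  for (k in seq_len(K))
    out[[paste0("cww", k)]] <- colMeans(X[vox[[k]], , drop = FALSE])
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == ncol(X))
    if ("subject_id" %in% names(covariates))
      out$subject_id <- covariates$subject_id
    out <- cbind(out, covariates[setdiff(names(covariates), "subject_id")])
  }
  out
}

#' Exclude values beyond 1.5 times the interquartile range
#'
#' Quartiles by linear interpolation on the sorted data; values outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] are excluded. Idempotent on the retained
#' values.
#'
#' @param values Numeric vector of length >= 4.
#' @return List: `retained` (values inside the fences), `excluded` (indices
#'   into `values`), `fences`.
#' @export
iqr_filter <- function(values) {
  if (length(values) < 4L) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  out <- values < fences[1] | values > fences[2]
  list(retained = values[!out], excluded = which(out), fences = fences)
}

# z-standardize a design data.frame column (binary coded 0/1 first)
standardize_col <- function(v) {
  if (is.character(v) || is.factor(v)) {
    lev <- sort(unique(as.character(v)))
    if (length(lev) > 2) stop("categorical predictors must be binary")
    v <- as.numeric(as.character(v) == lev[length(lev)])
  }
  s <- stats::sd(v)
  if (s == 0) stop("constant predictor")
  (v - mean(v)) / s
}

#' Determinant general linear models for pattern-wise pseudo-diffusivity
#'
#' For each outcome pattern, OLS of the z-standardized outcome on
#' z-standardized predictors (binary predictors coded 0/1 before
#' standardization), so coefficients are standardized effect sizes with
#' two-sided t-test p-values. With several outcomes the p-values are
#' FDR-adjusted across the whole outcome x predictor family.
#'
#' @param table Data frame from [cww_means] (values joined with covariates).
#' @param outcomes Outcome column name(s), e.g. `c("cww1", "cww2")`.
#' @param predictors Predictor column names, e.g. `c("age", "sex", "bpf")`.
#' @param iqr_exclude If `TRUE` (default), apply [iqr_filter] to each outcome
#'   before fitting.
#' @return Data frame: `outcome`, `predictor`, `beta` (standardized), `se`,
#'   `p`, `p_fdr`, `n`.
#' @export
fit_glm <- function(table, outcomes, predictors, iqr_exclude = TRUE) {
  res <- do.call(rbind, lapply(outcomes, function(oc) {
    y <- table[[oc]]
    if (is.null(y)) stop("outcome column not found: ", oc)
    keep <- seq_along(y)
    if (iqr_exclude) {
      flt <- iqr_filter(y)
      keep <- setdiff(keep, flt$excluded)
    }
    dat <- table[keep, , drop = FALSE]
    if (nrow(dat) <= length(predictors) + 1L)
      stop("too few subjects for the number of predictors")
    Z <- sapply(predictors, function(p) standardize_col(dat[[p]]))
    qz <- qr(cbind(1, Z))
    if (qz$rank < ncol(Z) + 1L) {
      drop_idx <- qz$pivot[seq(qz$rank + 1L, ncol(Z) + 1L)] - 1L
      stop("collinear predictors: ",
           paste(predictors[drop_idx], collapse = ", "))
    }
    yz <- standardize_col(dat[[oc]])
    fit <- stats::lm(yz ~ Z)
    sm <- summary(fit)$coefficients
    data.frame(outcome = oc, predictor = predictors,
               beta = sm[-1, 1], se = sm[-1, 2], p = sm[-1, 4],
               n = nrow(dat), row.names = NULL)
  }))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Mixed-effects aggregation across cohorts
#'
#' Random-intercept linear mixed model (REML) of the z-standardized pattern
#' outcome on z-standardized predictors with `(1 | cohort)`, for pooling two
#' or more cohorts; duplicated subjects must be removed beforehand. Fixed
#' effects are reported as standardized betas with Satterthwaite p-values,
#' FDR-adjusted across the outcome x predictor family.
#'
#' @param table Data frame with outcomes, predictors and a cohort column.
#' @param outcomes,predictors Column names as in [fit_glm].
#' @param cohort Cohort column name, default `"cohort"`.
#' @param iqr_exclude Apply [iqr_filter] per outcome (default `TRUE`).
#' @return Data frame: `outcome`, `predictor`, `beta`, `se`, `p`, `p_fdr`,
#'   `cohort_sd` (random-intercept SD), `n`.
#' @export
fit_mixed <- function(table, outcomes, predictors, cohort = "cohort",
                      iqr_exclude = TRUE) {
  if (is.null(table[[cohort]])) stop("cohort column not found: ", cohort)
  if (length(unique(table[[cohort]])) < 2L)
    stop("only one cohort present; use fit_glm instead")
  res <- do.call(rbind, lapply(outcomes, function(oc) {
    y <- table[[oc]]
    keep <- seq_along(y)
    if (iqr_exclude) keep <- setdiff(keep, iqr_filter(y)$excluded)
    dat <- table[keep, , drop = FALSE]
    df <- data.frame(.y = standardize_col(dat[[oc]]),
                     .cohort = factor(dat[[cohort]]))
    for (p in predictors) df[[p]] <- standardize_col(dat[[p]])
    fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = "+"),
                                   "+ (1 | .cohort)"))
    fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
    sm <- stats::coef(summary(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    data.frame(outcome = oc, predictor = predictors,
               beta = sm[-1, "Estimate"], se = sm[-1, "Std. Error"],
               p = sm[-1, "Pr(>|t|)"],
               cohort_sd = vc$sdcor[vc$grp == ".cohort"],
               n = nrow(dat), row.names = NULL)
  }))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Detect subjects with aberrant CSF flow patterns
#'
#' Per pattern, z-scores against the stratum mean and SD; a subject is
#' aberrant if (i) any pattern deviates by strictly more than 3 SD, or (ii)
#' two or more patterns deviate by strictly more than 2 SD. Strata are
#' cohorts by default (`per_cohort`) or the pooled sample.
#'
#' @param table Data frame from [cww_means]; pattern columns are those named
#'   `cww<k>`.
#' @param grouping `"per_cohort"` (needs a `cohort` column) or `"pooled"`.
#' @return Object of class `outlier_report`: data frame `report` with
#'   `subject_id`, `cohort`, `criterion_i`, `criterion_ii`, `aberrant`, and
#'   matrix `z` of per-pattern z-scores.
#' @export
detect_aberrant <- function(table, grouping = c("per_cohort", "pooled")) {
  grouping <- match.arg(grouping)
  cols <- grep("^cww[0-9]+$", names(table), value = TRUE)
  if (!length(cols)) stop("no cww<k> pattern columns found")
  strata <- if (grouping == "per_cohort") {
    if (is.null(table$cohort)) stop("per_cohort grouping needs a cohort column")
    as.character(table$cohort)
  } else rep("pooled", nrow(table))
  z <- matrix(NA_real_, nrow(table), length(cols),
              dimnames = list(NULL, cols))
  for (s in unique(strata)) {
    rows <- which(strata == s)
    if (length(rows) < 10L)
      stop("stratum '", s, "' has fewer than 10 subjects")
    for (j in seq_along(cols)) {
      v <- table[[cols[j]]][rows]
      sdv <- stats::sd(v)
      if (sdv == 0) stop("zero SD for ", cols[j], " in stratum '", s, "'")
      z[rows, j] <- (v - mean(v)) / sdv
    }
  }
  crit_i <- rowSums(abs(z) > 3) >= 1L
  crit_ii <- rowSums(abs(z) > 2) >= 2L
  rep_df <- data.frame(
    subject_id = if (!is.null(table$subject_id)) table$subject_id
                 else seq_len(nrow(table)),
    cohort = strata, criterion_i = crit_i, criterion_ii = crit_ii,
    aberrant = crit_i | crit_ii, row.names = NULL)
  structure(list(report = rep_df, z = z), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Aberrant CSF flow report:", sum(x$report$aberrant), "of",
      nrow(x$report), "subjects flagged (criterion i:",
      sum(x$report$criterion_i), ", criterion ii:",
      sum(x$report$criterion_ii), ")\n")
  invisible(x)
}

#' Fisher exact test on a 2 x 2 contingency table
#'
#' Exact hypergeometric test for enrichment (e.g. of clinically consequential
#' findings among subjects with aberrant flow): rows aberrant / non-aberrant,
#' columns finding present / absent. Two-sided by default (summing all tables
#' with point probability at most that observed); `"greater"` is the upper
#' tail.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filling the table by rows.
#' @param sided `"two"` or `"greater"`.
#' @return The p-value.
#' @examples
#' fisher_exact(c(5, 33, 0, 252))   # 3.04e-5
#' @export
fisher_exact <- function(table, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  alt <- if (sided == "two") "two.sided" else "greater"
  stats::fisher.test(table, alternative = alt)$p.value
}
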