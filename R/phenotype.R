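#' Rank-based inverse-normal (quantile) normalization
#'
#' Maps a vector to normal scores through its ranks: value with rank r
#' becomes `qnorm((r - offset) / (n - 2 * offset + 1))`. The default Blom
#' offset 3/8 gives quantiles `(r - 3/8) / (n + 1/4)`. Ties receive average
#' ranks. The output depends on the input only through its ranks, so any
#' monotone transform of the input gives identical output.
#'
#' @param x Numeric vector, length >= 3, non-constant, no missing values.
#' @param offset Rank offset in \[0, 0.5\] (Blom 3/8 by default).
#' @return Numeric vector of normal scores.
#' @export
quantile_normalize <- function(x, offset = 3 / 8) {
  if (anyNA(x)) stop("missing values in input to quantile_normalize()")
  n <- length(x)
  if (n < 3) stop("quantile normalization needs at least 3 observations")
  if (max(x) == min(x)) stop("constant input cannot be quantile normalized")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

# Quantile-normalize within each level of a grouping variable.
.stratified_qn <- function(x, group, offset = 3 / 8) {
  out <- numeric(length(x))
  for (g in unique(group)) {
    idx <- group == g
    out[idx] <- quantile_normalize(x[idx], offset = offset)
  }
  out
}

#' Residualize a vector on covariates by ordinary least squares
#'
#' Regresses `x` on an intercept plus the covariate columns and returns the
#' residuals, which are orthogonal to the intercept and every covariate.
#'
#' @param x Numeric vector.
#' @param covariates Numeric matrix (n x c) or `NULL` for intercept only.
#' @return Residual vector.
#' @export
residualize <- function(x, covariates = NULL) {
  if (is.null(covariates)) return(x - mean(x))
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == length(x))
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qx, x)
}

#' Prepare outcome and exposure vectors for block regression
#'
#' Produces regression-ready outcome and exposure vectors for the three
#' supported variable-type combinations.
#'
#' Continuous outcome and exposure: both are quantile normalized, regressed
#' on the covariates and re-normalized; the exposure is then residualized
#' out of the outcome (recording the exposure-outcome coefficient of
#' determination `r2_ey`), the outcome is re-normalized, an optional
#' heteroscedasticity adjustment rescales the outcome by the fitted
#' magnitude of its residuals on the exposure, and a final orthogonalization
#' pass leaves the outcome exactly orthogonal to the exposure and every
#' covariate.
#'
#' Dichotomous exposure: the 0/1 exposure is left untouched and the
#' (covariate-residualized) outcome is quantile normalized within each
#' exposure group separately.
#'
#' Dichotomous outcome: the 0/1 outcome is standardized to mean 0, sd 1, the
#' sample prevalence recorded, and the (covariate-residualized, normalized)
#' exposure is quantile normalized within each outcome group separately.
#'
#' @param y Outcome vector (continuous, or 0/1 when dichotomous).
#' @param e Exposure vector (continuous, or 0/1 when dichotomous).
#' @param covariates Optional numeric covariate matrix (e.g. age, sex,
#'   genetic principal components).
#' @param outcome_type `"continuous"` or `"dichotomous"`.
#' @param exposure_type `"continuous"` or `"dichotomous"`.
#' @param hetero_adjust `"scale-on-e"` (default) rescales the continuous
#'   outcome by the OLS fit of its absolute residuals on the exposure;
#'   `"none"` skips the adjustment.
#' @return A `prepared_cohort` with fields `y`, `e`, `covariates`, `r2_ey`,
#'   `outcome_type`, `exposure_type` and (dichotomous outcomes) `prevalence`.
#' @export
prepare <- function(y, e, covariates = NULL,
                    outcome_type = c("continuous", "dichotomous"),
                    exposure_type = c("continuous", "dichotomous"),
                    hetero_adjust = c("scale-on-e", "none")) {
  outcome_type <- match.arg(outcome_type)
  exposure_type <- match.arg(exposure_type)
  hetero_adjust <- match.arg(hetero_adjust)
  if (outcome_type == "dichotomous" && exposure_type == "dichotomous") {
    stop("dichotomous outcome with dichotomous exposure is not supported")
  }
  if (anyNA(y) || anyNA(e)) {
    stop("missing values in y or e; exclude incomplete individuals first ",
         "(mean imputation of outcome/exposure is refused)")
  }
  stopifnot(length(y) == length(e))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(y))
  }
  prevalence <- NULL

  if (outcome_type == "continuous" && exposure_type == "continuous") {
    y1 <- quantile_normalize(residualize(quantile_normalize(y), covariates))
    e1 <- quantile_normalize(residualize(quantile_normalize(e), covariates))
    fit_r2 <- stats::cor(y1, e1)^2
    y2 <- quantile_normalize(residualize(y1, e1))
    if (hetero_adjust == "scale-on-e") {
      fitted_scale <- abs(y2) - residualize(abs(y2), e1)
      fitted_scale <- pmax(fitted_scale, 0.1 * mean(abs(y2)))
      y2 <- quantile_normalize(y2 / fitted_scale)
    }
    y_prep <- residualize(y2, cbind(covariates, exposure = e1))
    e_prep <- e1
    r2_ey <- fit_r2
  } else if (exposure_type == "dichotomous") {
    e_chk <- .check_dichotomous(e, "exposure")
    y1 <- residualize(quantile_normalize(y), covariates)
    y_prep <- .stratified_qn(y1, e_chk)
    r2_ey <- stats::cor(y1, e_chk)^2
    e_prep <- e_chk
  } else { # dichotomous outcome, continuous exposure
    y_chk <- .check_dichotomous(y, "outcome")
    prevalence <- mean(y_chk)
    y_prep <- as.vector(scale(y_chk))
    e1 <- quantile_normalize(residualize(quantile_normalize(e), covariates))
    r2_ey <- stats::cor(y_prep, e1)^2
    e_prep <- .stratified_qn(e1, y_chk)
  }

  structure(list(y = y_prep, e = e_prep, covariates = covariates,
                 r2_ey = r2_ey, outcome_type = outcome_type,
                 exposure_type = exposure_type, prevalence = prevalence,
                 hetero_adjust = hetero_adjust),
            class = "prepared_cohort")
}

.check_dichotomous <- function(x, what) {
  ux <- sort(unique(x))
  if (!all(ux %in% c(0, 1)) || length(ux) != 2) {
    stop("dichotomous ", what, " must take exactly the values 0 and 1")
  }
  counts <- table(x)
  if (min(counts) < 30) {
    stop("dichotomous ", what, " has a group with fewer than 30 individuals; ",
         "stratified quantile normalization would be unstable")
  }
  as.numeric(x)
}

#' @export
print.prepared_cohort <- function(x, ...) {
  cat(sprintf("prepared_cohort: n = %d, outcome %s, exposure %s, r2_ey = %.4f\n",
              length(x$y), x$outcome_type, x$exposure_type, x$r2_ey))
  if (!is.null(x$prevalence)) {
    cat(sprintf("  sample prevalence: %.3f\n", x$prevalence))
  }
  invisible(x)
}

#' Build the interaction matrix for one genotype block
#'
#' Forms the column-wise product of a standardized genotype block with the
#' prepared exposure, then quantile normalizes every column (continuous
#' exposure) or standardizes it to mean 0, sd 1 (dichotomous exposure).
#'
#' @param G_block Standardized genotype matrix (n x m).
#' @param e_prepared Prepared exposure vector of length n.
#' @param exposure_type `"continuous"` or `"dichotomous"`.
#' @return Interaction matrix of the same shape as `G_block`.
#' @export
build_interaction_block <- function(G_block, e_prepared,
                                    exposure_type = c("continuous", "dichotomous")) {
  exposure_type <- match.arg(exposure_type)
  G_block <- as.matrix(G_block)
  if (nrow(G_block) != length(e_prepared)) {
    stop("shape mismatch: genotype block has ", nrow(G_block),
         " rows but exposure has length ", length(e_prepared))
  }
  W <- G_block * e_prepared
  if (exposure_type == "continuous") {
    .qn_matrix(W)
  } else {
    .scale_columns(W)
  }
}

# Columnwise quantile normalization with a precomputed normal-score lookup.
# Ties are essentially impossible in products of standardized genotypes with
# a continuous exposure; any tied column falls back to the general routine.
.qn_matrix <- function(W, offset = 3 / 8) {
  n <- nrow(W)
  lookup <- stats::qnorm((seq_len(n) - offset) / (n - 2 * offset + 1))
  out <- W
  for (j in seq_len(ncol(W))) {
    o <- order(W[, j])
    if (any(W[o[-1], j] == W[o[-n], j])) {
      out[, j] <- quantile_normalize(W[, j], offset = offset)
    } else {
      out[o, j] <- lookup
    }
  }
  out
}
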