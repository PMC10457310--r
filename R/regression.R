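#' Direct least-squares solve via QR factorization
#'
#' Computes the ordinary least-squares coefficients of `y` on the columns of
#' `U`. The mathematical contract is the normal-equation solution
#' `(U'U)^{-1} U'y`; the computation uses a (LAPACK) QR factorization for
#' numerical stability rather than an explicit inverse.
#'
#' @param U Predictor matrix, n x m with n > m.
#' @param y Response vector of length n.
#' @param method `"chol"` (default) forms the Gram matrix once and solves by
#'   Cholesky -- the fast route for tall standardized genotype blocks --
#'   falling back to QR automatically when the factorization fails or the
#'   Gram diagonal ratio signals trouble; `"qr"` forces the QR route.
#' @param rcond_tol Smallest acceptable ratio of extreme diagonal magnitudes
#'   of the triangular factor; below it the system is declared
#'   ill-conditioned.
#' @return Coefficient vector of length m.
#' @export
solve_direct <- function(U, y, method = c("chol", "qr"), rcond_tol = 1e-12) {
  method <- match.arg(method)
  U <- as.matrix(U)
  stopifnot(nrow(U) == length(y))
  if (nrow(U) <= ncol(U)) stop("need more observations than predictors")
  if (method == "chol") {
    G <- crossprod(U)
    R <- tryCatch(chol(G), error = function(e) NULL)
    if (!is.null(R)) {
      d <- diag(R)
      if (min(d)^2 >= rcond_tol * max(d)^2) {
        return(as.vector(backsolve(R, forwardsolve(t(R), crossprod(U, y)))))
      }
    }
    # fall through to the QR route on failure
  }
  qu <- qr(U, LAPACK = TRUE)
  d <- abs(diag(qr.R(qu)))
  if (min(d) < rcond_tol * max(d)) {
    stop(sprintf("ill-conditioned system: diagonal ratio %.3e below tolerance %.1e",
                 min(d) / max(d), rcond_tol))
  }
  as.vector(qr.coef(qu, y))
}

#' Conjugate-gradient least-squares solve
#'
#' Solves the normal equations `U'U beta = U'y` iteratively with a
#' Jacobi-preconditioned conjugate gradient. The Gram matrix is never
#' materialized: every iteration uses the matrix-free product `U'(U v)`, so
#' memory stays at O(nm) however large m is. Iteration stops when the
#' relative normal-equation residual drops below `tol`.
#'
#' @param U Predictor matrix, n x m.
#' @param y Response vector of length n.
#' @param tol Relative residual tolerance (default 1e-8).
#' @param max_iter Iteration cap; defaults to `10 * m + 100`. Non-convergence
#'   is an error carrying the final residual norm.
#' @return Coefficient vector of length m.
#' @export
solve_cg <- function(U, y, tol = 1e-8, max_iter = NULL) {
  U <- as.matrix(U)
  stopifnot(nrow(U) == length(y), tol > 0)
  m <- ncol(U)
  if (is.null(max_iter)) max_iter <- 10 * m + 100
  b <- as.vector(crossprod(U, y))
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(numeric(m))
  dprec <- colSums(U^2)
  dprec[dprec == 0] <- 1
  x <- numeric(m)
  r <- b
  z <- r / dprec
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- as.vector(crossprod(U, U %*% p))
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bnorm <= tol) return(x)
    z <- r / dprec
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("conjugate gradient did not converge in %d iterations; relative residual %.3e",
               max_iter, sqrt(sum(r^2)) / bnorm))
}

#' Per-block R-squared and adjusted R-squared
#'
#' Fits `y` on a predictor block by least squares, computes the coefficient
#' of determination as the variance of the fitted values over the variance of
#' the (centered) response, and applies the Wherry small-sample correction
#' `adj = 1 - (1 - R2) (n - 1) / (n - m - 1)`, which is unbiased to first
#' order under the null. The asymptotic sampling variance of the adjusted
#' R-squared is attached via [r2_variance()].
#'
#' @param U Predictor matrix (standardized columns), n x m.
#' @param y Mean-centered response vector.
#' @param solver `"direct"` (QR) or `"cg"` (conjugate gradient).
#' @param r2_ey Exposure-outcome coefficient of determination entering the
#'   variance formula (default 0).
#' @param block_id Optional identifier carried through to the result.
#' @param tol,max_iter Passed to [solve_cg()].
#' @return A `block_r2` object: `block`, `m`, `n`, `r2_raw`, `r2_adj`,
#'   `beta` and `variance`.
#' @export
block_r2 <- function(U, y, solver = c("direct", "cg"), r2_ey = 0,
                     block_id = NA, tol = 1e-8, max_iter = NULL) {
  solver <- match.arg(solver)
  U <- as.matrix(U)
  n <- length(y)
  m <- ncol(U)
  if (m == 0) { # degenerate block explains nothing by definition
    return(structure(list(block = block_id, m = 0L, n = n, r2_raw = 0,
                          r2_adj = 0, beta = numeric(0), variance = 0),
                     class = "block_r2"))
  }
  stopifnot(nrow(U) == n)
  if (n <= 10 * m) {
    warning(sprintf("block has n = %d <= 10 m = %d; estimates may be unstable",
                    n, 10 * m))
  }
  beta <- switch(solver,
                 direct = solve_direct(U, y),
                 cg = solve_cg(U, y, tol = tol, max_iter = max_iter))
  yhat <- as.vector(U %*% beta)
  yc <- y - mean(y)
  r2_raw <- sum((yhat - mean(yhat))^2) / sum(yc^2)
  r2_raw <- min(max(r2_raw, 0), 1)
  r2_adj <- 1 - (1 - r2_raw) * (n - 1) / (n - m - 1)
  variance <- r2_variance(min(max(r2_adj, 0), 1 - 1e-12), n, m, r2_ey = r2_ey)
  structure(list(block = block_id, m = as.integer(m), n = as.integer(n),
                 r2_raw = r2_raw, r2_adj = r2_adj, beta = beta,
                 variance = variance),
            class = "block_r2")
}

#' @export
print.block_r2 <- function(x, ...) {
  cat(sprintf("block_r2 [%s]: m = %d, n = %d, R2 = %.4f, adj R2 = %.4f (SE %.4f)\n",
              x$block, x$m, x$n, x$r2_raw, x$r2_adj, sqrt(x$variance)))
  invisible(x)
}
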