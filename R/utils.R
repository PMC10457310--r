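# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic operations in the package draw from streams keyed by a
#' master integer seed, an operation tag and a replicate number, so that
#' replicates and operations are independently reproducible.
#'
#' @param master Integer master seed.
#' @param tag Character tag naming the operation.
#' @param rep Replicate number (default 0).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, tag = "", rep = 0) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  if (length(h) == 0) h <- 0
  mod <- 2147483647
  s <- (abs(master) %% mod)
  s <- (s * 48271 + h * 16807 + rep * 69621 + 12345) %% mod
  as.integer(s)
}

# Column-wise centering and unit-variance scaling without copies of attributes.
# Errors on zero-variance columns (callers translate into domain errors).
.scale_columns <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  sd <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  if (any(sd == 0)) {
    stop("zero-variance column(s): ", paste(which(sd == 0), collapse = ", "))
  }
  sweep(Xc, 2, sd, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
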