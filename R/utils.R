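#' Derive a reproducible child seed from a base seed and indices
#'
#' Counter-based scheme used throughout the experiment drivers so that every
#' (sweep row, replicate, stage) triple gets an independently reproducible
#' seed. The result is always a positive integer below 2^31.
#'
#' @param base integer base seed.
#' @param ... integer indices (row, replicate, stage, ...).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 2)
derive_seed <- function(base, ...) {
  idx <- c(...)
  m <- 2147483629 # largest prime < 2^31
  s <- (as.double(base) %% m)
  # multiplicative mixing; doubles hold products below 2^53 exactly
  for (i in idx) {
    s <- (s * 48271 + (as.double(i) + 1) * 16807) %% m
    s <- (s * 69621) %% m
  }
  as.integer(s %% 2147483399) + 1L
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

.assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                           integer = FALSE, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("`%s` = %g is outside the valid range %s%g, %g%s", name, x,
                 if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(TRUE)
}

#' Sample points uniformly on the unit sphere
#'
#' Draws i.i.d. standard normal vectors and normalizes them; zero draws are
#' resampled. This is the input distribution for Gaussian-process tasks and
#' for all kernel-theory calculations.
#'
#' @param n number of points.
#' @param D ambient dimension.
#' @param seed optional RNG seed.
#' @return an n x D matrix of unit-norm rows.
#' @export
runif_sphere <- function(n, D, seed = NULL) {
  .assert_scalar(n, "n", lower = 1, integer = TRUE)
  .assert_scalar(D, "D", lower = 1, integer = TRUE)
  .set_seed_if(seed)
  .runif_sphere(n, D)
}

# rows of i.i.d. N(0, 1) normalized to the unit sphere; zero rows resampled
.runif_sphere <- function(n, D) {
  X <- matrix(rnorm(n * D), n, D)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm < 1e-12)
  while (length(bad) > 0) {
    X[bad, ] <- rnorm(length(bad) * D)
    nrm[bad] <- sqrt(rowSums(X[bad, , drop = FALSE]^2))
    bad <- bad[nrm[bad] < 1e-12]
  }
  X / nrm
}

# solve A x = B for symmetric PSD A, falling back to an eigen pseudo-inverse
# when A is (numerically) singular; used for Gram-form least squares
.psd_solve <- function(A, B) {
  out <- tryCatch({
    R <- chol(A)
    backsolve(R, forwardsolve(t(R), B))
  }, error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  if (!any(pos)) return(matrix(0, nrow(A), NCOL(B)))
  V <- e$vectors[, pos, drop = FALSE]
  V %*% ((crossprod(V, B)) / e$values[pos])
}
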