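#' Analytic prediction of kernel-regression generalization error
#'
#' Predicts the relative mean-squared generalization error of a least
#' squares (or ridge) readout of an infinitely wide expansion layer trained
#' on P patterns, from the kernel eigenvalue spectrum and the target power
#' spectrum. The error takes the spectral-bias form
#' `Error = C1 * sum_alpha (c_alpha / (C2 + lambda_alpha))^2` (normalized by
#' the total target power), where the mode-independent constants are
#' realized through a self-consistent scale kappa:
#' \itemize{
#'   \item `kappa` solves `kappa = ridge + kappa * sum_alpha
#'     lambda_alpha / (P lambda_alpha + kappa)` (sums run over modes, i.e.
#'     degeneracy-weighted over degrees);
#'   \item `gamma_v = sum_alpha P lambda_alpha^2 / (P lambda_alpha + kappa)^2`
#'     is the mode-variance sum, with `1 / (1 - gamma_v)` the variance
#'     amplification factor;
#'   \item `C2 = kappa / P` and `C1 = C2^2 / (1 - gamma_v)`.
#' }
#' Modes with larger eigenvalues are learned first (contribute less error
#' at a given P); the ordering of eigenvalues across frequencies is what
#' makes the optimal coding level task-dependent.
#'
#' @param spectrum a [kernel_eigenvalues()] result.
#' @param target a [target_spectrum()] on the same D (degrees are truncated
#'   to the common range).
#' @param P number of training patterns (P = 0 returns error 1: nothing has
#'   been learned).
#' @param ridge explicit ridge parameter; 0 requests the ridgeless limit,
#'   stabilized internally with a jitter of `1e-9 * K(1)`.
#' @return an object of class `generalization_prediction` with fields
#'   `error`, `kappa`, `gamma_v`, `variance_factor`, `C1`, `C2`, `P`,
#'   `ridge`, and the per-degree error shares `degree_error_share`.
#' @export
#' @examples
#' ks <- kernel_eigenvalues(kernel_model(f = 0.3), D = 3, k_max = 40)
#' ts <- gp_target_spectrum(gamma = 1, D = 3, k_max = 40)
#' predict_generalization_error(ks, ts, P = 30)
predict_generalization_error <- function(spectrum, target, P, ridge = 0) {
  stopifnot(inherits(spectrum, "kernel_spectrum"),
            inherits(target, "target_spectrum"))
  if (spectrum$D != target$D)
    stop("kernel and target spectra have different sphere dimension",
         call. = FALSE)
  .assert_scalar(P, "P", lower = 0, integer = TRUE)
  .assert_scalar(ridge, "ridge", lower = 0)
  kmax <- min(max(spectrum$degree), max(target$degree))
  keep_s <- spectrum$degree <= kmax
  keep_t <- target$degree <= kmax
  lam <- spectrum$lambda[keep_s]
  Nk <- spectrum$degeneracy[keep_s]
  c2 <- target$power_per_mode[keep_t]
  total_power <- sum(Nk * c2)
  if (total_power <= 0) stop("target has zero power", call. = FALSE)
  trace <- sum(Nk * lam)
  if (ridge == 0) ridge <- 1e-9 * spectrum$kernel_trace
  if (P == 0) {
    kappa <- ridge + trace
    pred <- list(error = 1, kappa = kappa, gamma_v = 0, variance_factor = 1,
                 C2 = Inf, C1 = Inf,
                 degree_error_share = Nk * c2 / total_power)
  } else {
    gfun <- function(kappa) kappa - ridge - kappa * sum(Nk * lam / (P * lam + kappa))
    upper <- ridge + trace
    lower <- upper * 1e-16
    while (gfun(lower) > 0 && lower > .Machine$double.xmin) lower <- lower / 1e4
    if (gfun(lower) > 0 || gfun(upper) < -1e-12 * upper)
      stop("failed to bracket the self-consistent kappa", call. = FALSE)
    kappa <- uniroot(gfun, lower = lower, upper = upper,
                     tol = .Machine$double.eps^0.75 * upper)$root
    gamma_v <- sum(Nk * P * lam^2 / (P * lam + kappa)^2)
    if (gamma_v >= 1)
      stop(sprintf(paste0("mode-variance sum gamma_v = %.6f >= 1: prediction ",
                          "diverges (interpolation-threshold pathology)"),
                   gamma_v), call. = FALSE)
    mode_err <- Nk * c2 * kappa^2 / (P * lam + kappa)^2
    err <- sum(mode_err) / ((1 - gamma_v) * total_power)
    pred <- list(error = err, kappa = kappa, gamma_v = gamma_v,
                 variance_factor = 1 / (1 - gamma_v),
                 C2 = kappa / P, C1 = (kappa / P)^2 / (1 - gamma_v),
                 degree_error_share = mode_err / ((1 - gamma_v) * total_power))
  }
  structure(c(pred, list(P = P, ridge = ridge, D = spectrum$D,
                         degree = spectrum$degree[keep_s])),
            class = "generalization_prediction")
}

#' @export
print.generalization_prediction <- function(x, ...) {
  cat(sprintf(paste0("<generalization_prediction> P=%d: error %.4g ",
                     "(kappa %.3e, variance factor %.3f)\n"),
              x$P, x$error, x$kappa, x$variance_factor))
  invisible(x)
}
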