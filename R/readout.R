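#' Readout model container
#'
#' Linear Purkinje cell-like readout of expansion-layer activity:
#' `f_hat(x) = w . h(x) + bias`.
#'
#' @param w M x Q weight matrix.
#' @param bias optional length-Q bias (NULL for none).
#' @param method fitting procedure that produced the model.
#' @param ... extra fields (hyperparameters, diagnostics) stored alongside.
#' @return an object of class `readout_model`.
#' @export
readout_model <- function(w, bias = NULL,
                          method = c("lstsq", "ridge", "nonneg", "online"),
                          ...) {
  method <- match.arg(method)
  w <- if (is.matrix(w)) w else matrix(w, ncol = 1)
  structure(c(list(w = w, bias = bias, method = method), list(...)),
            class = "readout_model")
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("<readout_model> method=%s, %d weights x %d output(s)%s\n",
              x$method, nrow(x$w), ncol(x$w),
              if (!is.null(x$bias)) ", with bias" else ""))
  invisible(x)
}

#' Predict readout outputs for expansion activity
#'
#' @param object a [readout_model()].
#' @param activity an M x P activity matrix or `expansion_activity`.
#' @param ... unused.
#' @return a P x Q matrix of predictions.
#' @export
predict.readout_model <- function(object, activity, ...) {
  H <- if (inherits(activity, "expansion_activity")) activity$H else activity
  out <- crossprod(H, object$w)
  if (!is.null(object$bias)) out <- sweep(out, 2, object$bias, "+")
  out
}

.as_target_matrix <- function(Y) if (is.matrix(Y)) Y else matrix(Y, ncol = 1)

#' Fit the readout by unregularized least squares
#'
#' Returns the minimum-norm solution of `min_w ||Y - H' w||^2`. For the
#' usual M > P regime the solution is computed in Gram (kernel) form,
#' `w = H (H'H)^+ Y`, which is algebraically identical to the pseudo-inverse
#' solution but needs only a P x P factorization.
#'
#' @param H M x P expansion activity (or `expansion_activity`).
#' @param Y P x Q target matrix (vectors accepted).
#' @return a [readout_model()].
#' @export
fit_least_squares <- function(H, Y) {
  if (inherits(H, "expansion_activity")) H <- H$H
  Y <- .as_target_matrix(Y)
  stopifnot(ncol(H) == nrow(Y))
  if (nrow(H) >= ncol(H)) {
    alpha <- .psd_solve(crossprod(H), Y)
    w <- H %*% alpha
  } else {
    w <- .psd_solve(tcrossprod(H), H %*% Y)
  }
  readout_model(w, method = "lstsq")
}

#' Fit the readout by ridge regression
#'
#' Minimizes `sum_mu ||Y_mu - w . h_mu||^2 + M * alpha_ridge * ||w||^2`;
#' the regularization scale is multiplied by the expansion size M so that
#' `alpha_ridge` is comparable across network widths. Solved in whichever
#' of the primal/Gram forms is smaller.
#'
#' @param H M x P expansion activity (or `expansion_activity`).
#' @param Y P x Q targets.
#' @param alpha_ridge regularization parameter (>= 0).
#' @return a [readout_model()].
#' @export
fit_ridge <- function(H, Y, alpha_ridge) {
  if (inherits(H, "expansion_activity")) H <- H$H
  Y <- .as_target_matrix(Y)
  .assert_scalar(alpha_ridge, "alpha_ridge", lower = 0)
  stopifnot(ncol(H) == nrow(Y))
  M <- nrow(H)
  lam <- M * alpha_ridge
  if (lam == 0) {
    m <- fit_least_squares(H, Y)
    return(readout_model(m$w, method = "ridge", alpha_ridge = alpha_ridge))
  }
  if (M >= ncol(H)) {
    # push-through identity: (HH' + lam I)^-1 H Y = H (H'H + lam I)^-1 Y
    w <- H %*% .psd_solve(crossprod(H) + diag(lam, ncol(H)), Y)
  } else {
    w <- .psd_solve(tcrossprod(H) + diag(lam, M), H %*% Y)
  }
  readout_model(w, method = "ridge", alpha_ridge = alpha_ridge)
}

#' Fit a nonnegative readout with free bias
#'
#' Solves the convex quadratic program
#' `min_{w >= 0, b} sum_mu (y_mu - w . h_mu - b)^2`
#' by an active-set method (Lawson-Hanson nonnegative least squares with
#' the bias as a permanently passive column): variables enter the support
#' by steepest gradient violation, each subproblem is solved exactly by
#' least squares on the support, and infeasible steps are truncated at the
#' first variable to hit zero. Terminates in finitely many steps with the
#' Karush-Kuhn-Tucker conditions satisfied to `tol` relative to the
#' gradient scale. In the wide, interpolating regime the least-squares
#' optimum is non-unique (a polytope); among the optima the canonical
#' minimum-norm solution is returned, computed from the dual of the
#' nonnegative interpolation program. Models the sign constraint of
#' granule cell-to-Purkinje cell synapses; optimal solutions set a large
#' fraction of the weights exactly to zero ("silent synapses"), with the
#' delta-at-zero plus continuous-bulk weight distribution characteristic
#' of capacity-maximizing readouts.
#'
#' @param H M x P expansion activity (or `expansion_activity`).
#' @param y length-P nonnegative target vector (categorization targets
#'   should be mapped to \{0, 1\} and continuous targets to their absolute
#'   values beforehand).
#' @param tol relative KKT tolerance.
#' @param max_iter cap on active-set iterations; exceeding it raises an
#'   error with diagnostics.
#' @return a [readout_model()] with fields `objective`, `kkt_residual`,
#'   `iterations`.
#' @export
fit_nonnegative <- function(H, y, tol = 1e-8, max_iter = 1e4) {
  if (inherits(H, "expansion_activity")) H <- H$H
  y <- drop(y)
  stopifnot(is.numeric(y), ncol(H) == length(y))
  if (any(y < 0))
    stop("nonnegative readout requires nonnegative targets", call. = FALSE)
  M <- nrow(H)
  grad_scale <- max(2 * max(abs(H %*% y)), 2 * abs(sum(y)), 1)
  supp <- integer(0) # passive (positive-weight) set
  w_s <- numeric(0)
  b <- mean(y)
  resid <- y - b
  solve_support <- function(supp) {
    # exact least squares over [1, H[supp, ]'] via QR; rank-deficient
    # supports fall back to the minimum-norm solution
    Xs <- cbind(1, t(H[supp, , drop = FALSE]))
    qr.coef(qr(Xs), y)
  }
  it <- 0L
  kkt <- Inf
  repeat {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf(paste0("nonnegative readout did not converge: KKT residual ",
                          "%.3e (tolerance %.3e) after %d active-set steps"),
                   kkt, tol * grad_scale, max_iter), call. = FALSE)
    g <- -2 * drop(H %*% resid) # gradient wrt w
    g[supp] <- 0
    j <- which.min(g)
    kkt <- max(0, -g[j])
    if (kkt <= tol * grad_scale) break
    supp <- c(supp, j)
    w_try <- c(b, w_s, 0) # current feasible point over (bias, support)
    beta <- solve_support(supp)
    beta[is.na(beta)] <- 0
    # inner loop: back off along the segment to the unconstrained optimum
    # until all support weights are feasible, dropping blocking variables
    while (length(supp) > 0 && any(beta[-1] < 0)) {
      neg <- which(beta[-1] < 0)
      frac <- w_try[1 + neg] / (w_try[1 + neg] - beta[1 + neg])
      alpha <- min(frac)
      w_try <- w_try + alpha * (beta - w_try)
      drop_idx <- neg[frac <= alpha + 1e-12]
      supp <- supp[-drop_idx]
      w_try <- w_try[-(1 + drop_idx)]
      if (length(supp) == 0) {
        beta <- mean(y)
        break
      }
      beta <- solve_support(supp)
      beta[is.na(beta)] <- 0
    }
    b <- beta[1]
    w_s <- if (length(beta) > 1) pmax(beta[-1], 0) else numeric(0)
    pred <- b + if (length(supp)) drop(crossprod(H[supp, , drop = FALSE], w_s)) else 0
    resid <- y - pred
  }
  w <- rep(0, M)
  w[supp] <- w_s
  obj <- sum(resid^2)
  if (obj <= 1e-7 * max(1, sum(y^2))) {
    # the fit is exact, so the least-squares optimum is a polytope; return
    # the canonical minimum-norm interpolator (delta-at-zero plus
    # continuous-bulk weight distribution)
    mn <- .nonneg_min_norm(H, y, tol = tol)
    if (!is.null(mn))
      return(readout_model(mn$w, bias = mn$bias, method = "nonneg",
                           objective = mn$objective,
                           kkt_residual = mn$kkt_residual,
                           iterations = it + mn$iterations))
  }
  readout_model(w, bias = b, method = "nonneg", objective = obj,
                kkt_residual = kkt, iterations = it)
}

# minimum-norm nonnegative interpolation:
#   min 0.5 ||w||^2  s.t.  w >= 0, H' w + b 1 = y
# solved in the P-dimensional dual max_{1'nu = 0} -0.5||(H nu)_+||^2 + nu'y
# by semi-smooth Newton with backtracking; primal w = (H nu)_+.
# Returns NULL if the dual fails to converge (caller keeps the LS solution).
.nonneg_min_norm <- function(H, y, tol = 1e-8, max_iter = 200) {
  P <- length(y)
  center <- function(v) v - mean(v)
  qval <- function(nu) {
    w <- pmax(H %*% nu, 0)
    -0.5 * sum(w^2) + sum(nu * y)
  }
  yscale <- max(sqrt(sum(y^2)), 1e-12)
  nu <- center(y) / max(sum(colSums(H^2)) / ncol(H), 1)
  q0 <- qval(nu)
  for (it in seq_len(max_iter)) {
    w <- drop(H %*% nu)
    S <- which(w > 0)
    grad <- center(y - crossprod(H[S, , drop = FALSE], w[S]))
    if (sqrt(sum(grad^2)) <= tol * yscale) break
    if (length(S) == 0) {
      step <- grad # gradient ascent until some unit activates
    } else {
      A <- crossprod(H[S, , drop = FALSE]) # H_S' H_S, P x P
      diag(A) <- diag(A) + 1e-10 * max(diag(A), 1)
      Ai_g <- .psd_solve(A, cbind(grad, rep(1, P)))
      tau <- sum(Ai_g[, 1]) / sum(Ai_g[, 2]) # enforces 1' step = 0
      step <- drop(Ai_g[, 1] - tau * Ai_g[, 2])
    }
    t_ls <- 1
    for (bt in 1:60) {
      q1 <- qval(nu + t_ls * step)
      if (q1 > q0 + 1e-12 * abs(q0)) break
      t_ls <- t_ls / 2
    }
    if (bt == 60 && q1 <= q0) break # objective flat to machine precision
    nu <- nu + t_ls * step
    q0 <- q1
    if (it == max_iter) return(NULL)
  }
  w <- pmax(drop(H %*% nu), 0)
  fit <- drop(crossprod(H, w))
  b <- mean(y - fit)
  resid <- y - fit - b
  if (max(abs(resid)) > 1e-6 * max(1, yscale)) return(NULL)
  list(w = w, bias = b, objective = sum(resid^2),
       kkt_residual = max(abs(resid)), iterations = it)
}

#' Fraction of silent readout weights
#'
#' @param w a weight vector, or a [readout_model()] (its first output
#'   column is used).
#' @param tol weights at or below this are silent; defaults to
#'   `1e-6 * max(abs(w))`.
#' @return fraction in \[0, 1\].
#' @export
silent_fraction <- function(w, tol = NULL) {
  if (inherits(w, "readout_model")) w <- w$w[, 1]
  w <- drop(w)
  if (is.null(tol)) tol <- 1e-6 * max(abs(w))
  mean(w <= tol)
}

#' Fit the readout with an online climbing fiber-like rule
#'
#' Delta-rule learning in which the climbing fiber signal carries the
#' prediction error `c = y - w . h(x)` and every presentation of a pattern
#' updates the weights by `delta_w = eta * c * h(x)`. Patterns are shuffled
#' within each epoch; weights start at zero. On consistent problems with a
#' small learning rate this converges to the minimum-norm least-squares
#' interpolator.
#'
#' @param H M x P expansion activity (or `expansion_activity`).
#' @param y length-P target vector.
#' @param eta learning rate (> 0); default `0.7 / M`.
#' @param n_epochs number of passes over the training patterns.
#' @param seed optional RNG seed controlling the shuffles.
#' @return a [readout_model()] with a field `train_error` (final training
#'   MSE).
#' @export
fit_online_cf <- function(H, y, eta = NULL, n_epochs = 2e4, seed = NULL) {
  if (inherits(H, "expansion_activity")) H <- H$H
  y <- drop(y)
  stopifnot(ncol(H) == length(y))
  M <- nrow(H)
  P <- ncol(H)
  if (is.null(eta)) eta <- 0.7 / M
  .assert_scalar(eta, "eta", lower = 0, strict = TRUE)
  .assert_scalar(n_epochs, "n_epochs", lower = 1, integer = TRUE)
  .set_seed_if(seed)
  w <- rep(0, M)
  check_every <- max(1L, min(50L, n_epochs %/% 20L))
  best_err <- Inf
  for (ep in seq_len(n_epochs)) {
    for (mu in sample.int(P)) {
      h <- H[, mu]
      cf <- y[mu] - sum(w * h)
      w <- w + eta * cf * h
    }
    if (ep %% check_every == 0) {
      err <- mean((y - drop(crossprod(H, w)))^2)
      if (!is.finite(err) || err > 10 * best_err + 1e-12)
        stop(sprintf(paste0("online rule diverged at epoch %d (training MSE ",
                            "%.3e, best %.3e); reduce eta"), ep, err, best_err),
             call. = FALSE)
      best_err <- min(best_err, err)
    }
  }
  readout_model(w, method = "online", eta = eta, n_epochs = n_epochs,
                train_error = mean((y - drop(crossprod(H, w)))^2))
}

#' Evaluate a readout on held-out activity
#'
#' Continuous tasks score relative mean squared error,
#' `E[(y - y_hat)^2] / E[y^2]`, computed per target dimension and averaged
#' for multi-dimensional targets; an all-zero predictor therefore scores
#' exactly 1. Categorical tasks score the fraction of sign errors of
#' `w . h(x)`, with `sign(0)` taken as +1.
#'
#' @param model a [readout_model()].
#' @param H_test M x P_test activity (or `expansion_activity`).
#' @param Y_test matching targets.
#' @param task_kind `"continuous"` or `"categorical"`.
#' @return the scalar error.
#' @export
evaluate_readout <- function(model, H_test, Y_test,
                             task_kind = c("continuous", "categorical")) {
  task_kind <- match.arg(task_kind)
  pred <- predict(model, H_test)
  Y <- .as_target_matrix(Y_test)
  stopifnot(nrow(pred) == nrow(Y), ncol(pred) == ncol(Y))
  if (task_kind == "categorical") {
    s <- ifelse(pred >= 0, 1, -1)
    return(mean(s != Y))
  }
  denom <- colMeans(Y^2)
  if (any(denom == 0))
    stop("relative error undefined: a target dimension is identically zero",
         call. = FALSE)
  mean(colMeans((Y - pred)^2) / denom)
}
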