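#' Feature selection with an L1-regularized linear SVM
#'
#' Fits a linear support vector machine with squared-hinge loss and an L1
#' weight penalty,
#' \deqn{\min_{w,b}\; \|w\|_1 + C \sum_i \max(0,\, 1 - y_i (x_i^\top w + b))^2,}
#' by FISTA proximal-gradient descent with soft-thresholding, which drives
#' most weights to exactly zero. The features with non-zero weight are the
#' selected wavenumbers; larger `fs_C` retains more features. The solver is
#' deterministic: fixed initialization (zero weights), fixed power-iteration
#' start for the step size, no randomness.
#'
#' @param x Standardized feature matrix (rows = observations; wavenumber
#'   column names, if present, are propagated to the selection).
#' @param y Binary labels: 0/1, a two-level factor, or -1/+1.
#' @param fs_C Regularization parameter of the loss term (the study grid
#'   spans 0.05 to 0.5).
#' @param max_iter,tol Solver iteration cap and relative objective
#'   tolerance.
#' @return A list of class `feature_selection`: `selected_indices`,
#'   `selected_wavenumbers_cm1`, `weights` (signed, non-zero exactly on the
#'   selected indices), `intercept`, `fs_C`, `n_features`, `objective`.
#' @export
select_features_l1 <- function(x, y, fs_C, max_iter = 500, tol = 1e-9) {
  x <- as.matrix(x)
  y <- to_pm1(y)
  if (length(unique(y)) < 2L) {
    stop("Feature selection needs both classes present.", call. = FALSE)
  }
  if (length(y) != nrow(x)) stop("`x` and `y` lengths differ.", call. = FALSE)
  stopifnot(fs_C > 0)
  fit <- fista_l1_svm(x, y, fs_C, max_iter = max_iter, tol = tol)
  sel <- which(fit$w != 0)
  wn <- if (!is.null(colnames(x))) as.numeric(colnames(x)[sel]) else
    as.numeric(sel)
  structure(list(selected_indices = sel,
                 selected_wavenumbers_cm1 = wn,
                 weights = fit$w[sel],
                 intercept = fit$b,
                 fs_C = fs_C,
                 n_features = ncol(x),
                 objective = fit$objective),
            class = "feature_selection")
}

to_pm1 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (identical(u, c(-1, 1))) return(y)
  if (all(y %in% c(0, 1))) return(2 * y - 1)
  if (length(u) == 2L) return(ifelse(y == u[2L], 1, -1))
  stop("Labels must be binary.", call. = FALSE)
}

# FISTA on f(w,b) = C * sum(squared hinge) with g(w) = ||w||_1 (intercept
# unpenalized). Squared hinge is differentiable with 2C*L_max(X'X)-Lipschitz
# gradient; the prox of the l1 term is soft-thresholding, giving exact zeros.
fista_l1_svm <- function(x, y, C, max_iter = 500, tol = 1e-9) {
  n <- nrow(x); p <- ncol(x)
  lip <- 2 * C * spectral_norm_sq(cbind(x, 1))
  step <- 1 / max(lip, .Machine$double.eps)

  objective <- function(w, b) {
    h <- pmax(0, 1 - y * (drop(x %*% w) + b))
    sum(abs(w)) + C * sum(h^2)
  }
  grad <- function(w, b) {
    h <- pmax(0, 1 - y * (drop(x %*% w) + b))
    gw <- -2 * C * drop(crossprod(x, y * h))
    gb <- -2 * C * sum(y * h)
    list(w = gw, b = gb)
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  w <- numeric(p); b <- 0
  zw <- w; zb <- b; tk <- 1
  obj <- objective(w, b)
  for (iter in seq_len(max_iter)) {
    g <- grad(zw, zb)
    w_new <- soft(zw - step * g$w, step)
    b_new <- zb - step * g$b
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zw <- w_new + ((tk - 1) / t_new) * (w_new - w)
    zb <- b_new + ((tk - 1) / t_new) * (b_new - b)
    obj_new <- objective(w_new, b_new)
    if (obj_new > obj) {  # monotone restart
      zw <- w_new; zb <- b_new; t_new <- 1
    }
    converged <- abs(obj - obj_new) <= tol * max(1, abs(obj))
    w <- w_new; b <- b_new; tk <- t_new; obj <- obj_new
    if (converged && iter > 10L) break
  }
  list(w = w, b = b, objective = obj, iterations = iter)
}

# Largest eigenvalue of X'X by power iteration with a fixed start vector.
spectral_norm_sq <- function(x) {
  p <- ncol(x)
  v <- rep(1 / sqrt(p), p)
  ev <- 0
  for (i in seq_len(60)) {
    u <- drop(crossprod(x, x %*% v))
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(0)
    v_new <- u / nu
    ev_new <- nu
    if (abs(ev_new - ev) <= 1e-8 * max(1, ev_new) && i > 5L) {
      return(ev_new)
    }
    v <- v_new; ev <- ev_new
  }
  ev * 1.01  # modest safety margin if power iteration has not settled
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> fs_C = %g: %d of %d features selected\n",
              x$fs_C, length(x$selected_indices), x$n_features))
  invisible(x)
}
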