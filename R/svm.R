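#' Train a linear support vector machine (deterministic SMO)
#'
#' Solves the C-SVC dual (hinge loss, `1/2 ||w||^2 + C * sum xi`) by
#' sequential minimal optimization with maximal-violating-pair working-set
#' selection, fixed tolerance and lowest-index tie-breaking: the solution
#' is deterministic given the data — no internal randomization. The linear
#' kernel matrix is formed explicitly (sample counts here are small).
#'
#' @param X samples x features matrix.
#' @param y labels: a factor/character with two levels, or numeric ±1. For
#'   factors the positive class (+1) is the second sorted level.
#' @param C regularization parameter (> 0), default 1.
#' @param tol KKT violation tolerance (default 1e-6).
#' @param max_passes iteration cap in multiples of `n` (default 2000).
#' @return list of class `linear_svm`: `w` (weight vector), `b` (bias),
#'   `alpha`, `levels` (NULL for numeric input), `iterations`, `converged`.
#' @export
train_linear_svm <- function(X, y, C = 1, tol = 1e-6, max_passes = 2000) {
  assert_scalar_num(C, "C", lower = 1e-12)
  X <- as.matrix(X)
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    yy <- as.integer(y)
    levels <- NULL
  } else {
    f <- factor(y)
    if (nlevels(f) != 2)
      stopf("invalid parameter: need exactly two classes, got %d", nlevels(f))
    yy <- ifelse(as.integer(f) == 2L, 1L, -1L)
    levels <- levels(f)
  }
  if (length(unique(yy)) < 2) stopf("invalid parameter: single-class input")
  K <- tcrossprod(X)
  fit <- smo_solve(K, yy, C, tol, as.integer(max_passes))
  w <- drop(crossprod(X, fit$alpha * yy))
  structure(list(w = w, b = fit$b, alpha = fit$alpha, y = yy,
                 levels = levels, iterations = fit$iterations,
                 converged = fit$converged),
            class = "linear_svm")
}

#' Decision values and predicted labels from a linear SVM
#'
#' @param object a `linear_svm` fit.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return list with `decision` (w.x + b) and `label` (±1, or the original
#'   factor levels when the fit was trained on a factor).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  dec <- drop(as.matrix(newdata) %*% object$w) + object$b
  pm <- ifelse(dec >= 0, 1L, -1L)
  lab <- if (is.null(object$levels)) pm else object$levels[ifelse(pm == 1L, 2L, 1L)]
  list(decision = dec, label = lab)
}
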