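# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation paths they check.

# Exhaustive KKT active-set enumeration for the C-SVC dual on tiny problems:
# every point is assigned to {alpha = 0, alpha = C, free}; free alphas and
# the bias solve the margin equations + the equality constraint, and the
# assignment is feasible iff box and margin inequalities hold. The feasible
# solution with the smallest primal objective is the optimum.
svm_qp_oracle <- function(X, y, C = 1, eps = 1e-7) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(n <= 10, all(y %in% c(-1, 1)))
  K <- tcrossprod(X)
  states <- as.matrix(do.call(expand.grid, rep(list(0:2), n)))
  best <- NULL
  for (s in seq_len(nrow(states))) {
    st <- states[s, ]
    Fr <- which(st == 2)
    Up <- which(st == 1)
    alpha <- numeric(n)
    alpha[Up] <- C
    nf <- length(Fr)
    # unknowns: alpha[Fr], b
    A <- matrix(0, nf + 1, nf + 1)
    rhs <- numeric(nf + 1)
    if (nf > 0) {
      for (r in seq_len(nf)) {
        i <- Fr[r]
        A[r, seq_len(nf)] <- y[Fr] * K[i, Fr]
        A[r, nf + 1] <- 1
        rhs[r] <- y[i] - sum(C * y[Up] * K[i, Up])
      }
    }
    A[nf + 1, seq_len(nf + 1)] <- c(y[Fr], 0)
    rhs[nf + 1] <- -sum(C * y[Up])
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    if (nf > 0) alpha[Fr] <- sol[seq_len(nf)]
    b <- sol[nf + 1]
    if (nf == 0 && abs(rhs[1]) > eps) next  # equality constraint unmet
    if (any(alpha[Fr] < eps | alpha[Fr] > C - eps)) next
    u <- drop(K %*% (alpha * y))
    marg <- y * (u + b)
    if (any(marg[st == 0] < 1 - 1e-5)) next
    if (any(marg[Up] > 1 + 1e-5)) next
    w <- drop(crossprod(X, alpha * y))
    obj <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (X %*% w + b)))
    if (is.null(best) || obj < best$obj - 1e-9)
      best <- list(w = w, b = b, alpha = alpha, obj = obj)
  }
  best
}

# Naive exhaustive sign-flip max-t enumeration (loop-based, no shared code
# with the package's vectorized implementation)
maxt_exhaustive_oracle <- function(D, alpha = 0.05) {
  n <- nrow(D)
  R <- ncol(D)
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  t_obs <- apply(D, 2, tstat)
  tmax <- numeric(2^n)
  for (p in seq_len(2^n)) {
    bits <- as.integer(intToBits(p - 1))[seq_len(n)]
    s <- ifelse(bits == 1, 1, -1)
    tmax[p] <- max(apply(D * s, 2, tstat))
  }
  p_fwe <- vapply(t_obs, function(t0) mean(tmax >= t0 - 1e-10), numeric(1))
  list(t_obs = t_obs, p_fwe = p_fwe, tmax = tmax)
}
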