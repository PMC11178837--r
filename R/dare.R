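# Discrete algebraic Riccati equation, Kalman-filtering form with
# correlated process/observation noise:
#
#   P = A P A' + Q - (A P C' + S) (C P C' + R)^{-1} (A P C' + S)'
#
# Returned alongside the steady-state gain K = (A P C' + S) (C P C' + R)^{-1}
# and the innovation covariance V = C P C' + R.
#
# Solved by the structure-preserving doubling algorithm (SDA) after the
# standard reduction that removes the cross-covariance S; quadratically
# convergent for the stabilisable/detectable systems arising from stable
# VAR models.  `method = "iterate"` runs the plain Kalman covariance
# recursion instead and is kept as an independent oracle for tests.
solve_dare <- function(A, C, Q, R, S = NULL, method = c("sda", "iterate"),
                       tol = 1e-12, max_iter = 300) {
  method <- match.arg(method)
  m <- nrow(A)
  if (is.null(S)) S <- matrix(0, m, nrow(C))
  Rinv_C <- solve(R, C)
  Ab <- A - S %*% Rinv_C
  Qb <- Q - S %*% solve(R, t(S))
  Qb <- (Qb + t(Qb)) / 2

  if (method == "sda") {
    # estimator-form DARE  X = Ab X Ab' + Qb - Ab X C'(R + C X C')^{-1} C X Ab'
    # is the dual of the control form with (A*, B*) = (Ab', C'); SDA-1:
    Ak <- t(Ab)
    Gk <- crossprod(Rinv_C, C)        # C' R^{-1} C
    Hk <- Qb
    I <- diag(m)
    conv <- FALSE
    for (it in seq_len(100)) {
      W <- solve(I + Gk %*% Hk)
      A1 <- Ak %*% W %*% Ak
      G1 <- Gk + Ak %*% W %*% Gk %*% t(Ak)
      H1 <- Hk + t(Ak) %*% Hk %*% W %*% Ak
      delta <- max(abs(H1 - Hk))
      Ak <- A1; Gk <- (G1 + t(G1)) / 2; Hk <- (H1 + t(H1)) / 2
      if (delta < tol * max(1, max(abs(Hk)))) { conv <- TRUE; break }
    }
    if (!conv)
      stop("Riccati (DARE) doubling iteration failed to converge")
    P <- Hk
  } else {
    P <- Qb
    conv <- FALSE
    for (it in seq_len(max_iter * 100)) {
      APC <- Ab %*% P %*% t(C)
      Pn <- Ab %*% P %*% t(Ab) + Qb -
        APC %*% solve(C %*% P %*% t(C) + R, t(APC))
      Pn <- (Pn + t(Pn)) / 2
      delta <- max(abs(Pn - P))
      P <- Pn
      if (delta < tol * max(1, max(abs(P)))) { conv <- TRUE; break }
    }
    if (!conv) stop("Riccati fixed-point iteration failed to converge")
  }

  V <- C %*% P %*% t(C) + R
  V <- (V + t(V)) / 2
  K <- t(solve(V, t(A %*% P %*% t(C) + S)))
  list(P = P, K = K, V = V)
}
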