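# Shared fixtures, built in code.

# Centered pair with orthonormal columns sharing one latent: on such data
# classical CCA reduces to the SVD of X'Y, so the identity-covariance
# solvers and the closed-form oracle agree to numerical precision.
gen_whitened_pair <- function(n, p, q, seed, strength = 2) {
  set.seed(seed)
  z <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + strength * z
  Y <- matrix(rnorm(n * q), n, q)
  Y[, 1] <- Y[, 1] + strength * z
  whiten <- function(A) qr.Q(qr(scale(A, scale = FALSE)))
  list(X = whiten(X), Y = whiten(Y))
}

# Random symmetric nonnegative adjacency with zero diagonal.
random_adjacency <- function(p, seed) {
  set.seed(seed)
  A <- matrix(runif(p * p), p, p)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

support_f1 <- function(est, truth) {
  if (length(est) == 0) return(0)
  tp <- length(intersect(est, truth))
  prec <- tp / length(est)
  rec <- tp / length(truth)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

aligned_cosine <- function(w_est, w_true) {
  abs(sum(w_est * w_true)) / sqrt(sum(w_est^2) * sum(w_true^2))
}

mean_offdiag <- function(rho) mean(abs(rho[upper.tri(rho)]), na.rm = TRUE)

monotone_trace <- function(fit, tol = 1e-8) {
  all(vapply(fit$components, function(cp) {
    tr <- cp$convergence$objective_trace
    length(tr) < 2 || all(diff(tr) >= -tol * pmax(1, abs(tr[-length(tr)])))
  }, logical(1)))
}
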