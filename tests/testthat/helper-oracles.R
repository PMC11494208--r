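# Independent oracles used to cross-check the closed-form divergences.

# log density of rows of X under N(mu, S), via Cholesky
gauss_logpdf <- function(X, mu, S) {
  R <- chol(S)
  z <- forwardsolve(t(R), t(X) - mu)
  -0.5 * colSums(z * z) - sum(log(diag(R))) -
    0.5 * nrow(S) * log(2 * pi)
}

# Monte-Carlo KLD estimate E_P1[log p1 - log p2] with standard error
mc_kld <- function(P1, P2, n = 1e6) {
  X <- MASS::mvrnorm(n, P1$mean, P1$cov)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  d <- gauss_logpdf(X, P1$mean, P1$cov) - gauss_logpdf(X, P2$mean, P2$cov)
  list(est = mean(d), se = stats::sd(d) / sqrt(n))
}

# Monte-Carlo Bhattacharyya: -log E_P1[ sqrt(p2/p1) ]
mc_bhattacharyya <- function(P1, P2, n = 1e6) {
  X <- MASS::mvrnorm(n, P1$mean, P1$cov)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  r <- exp(0.5 * (gauss_logpdf(X, P2$mean, P2$cov) -
                    gauss_logpdf(X, P1$mean, P1$cov)))
  -log(mean(r))
}

# random invertible affine map with bounded condition number
random_affine <- function(k) {
  Q1 <- qr.Q(qr(matrix(rnorm(k * k), k)))
  Q2 <- qr.Q(qr(matrix(rnorm(k * k), k)))
  A <- Q1 %*% diag(runif(k, 0.5, 2), k) %*% Q2
  list(A = A, b = rnorm(k))
}
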