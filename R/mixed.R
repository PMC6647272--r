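# Spectral (eigendecomposition) REML for the single-kinship mixed model
#   y = X b + g + e,   g ~ N(0, sigma_g^2 K),  e ~ N(0, sigma_e^2 I)
# The variance ratio delta = sigma_e^2 / sigma_g^2 is profiled out on the
# spectrum of the kinship projected off the fixed effects (EMMA-style), which
# reduces REML to a one-dimensional maximization.

spectral_reml <- function(y, X, K, delta_grid = 10^seq(-6, 8, length.out = 60)) {
  n <- length(y)
  q <- qr(X)
  if (q$rank < ncol(X)) stop2("fixed-effect design is rank deficient")
  Qc <- qr.Q(q, complete = TRUE)[, (q$rank + 1):n, drop = FALSE]  # basis of X-perp
  Ks <- crossprod(Qc, K %*% Qc)
  Ks <- (Ks + t(Ks)) / 2
  eg <- eigen(Ks, symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, crossprod(Qc, y))
  m <- n - q$rank
  # restricted log-likelihood up to a constant, profiled over sigma_g^2
  rll <- function(delta) {
    w <- xi + delta
    s2 <- sum(yt^2 / w) / m
    if (s2 <= 0) return(-Inf)
    -0.5 * (m * log(s2) + sum(log(w)) + m)
  }
  vals <- vapply(delta_grid, rll, numeric(1))
  best <- which.max(vals)
  lo <- delta_grid[max(1, best - 1)]
  hi <- delta_grid[min(length(delta_grid), best + 1)]
  opt <- stats::optimize(function(ld) rll(exp(ld)), c(log(lo), log(hi)),
                         maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  sigma_g2 <- sum(yt^2 / (xi + delta)) / m
  list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
       reml_loglik = opt$objective)
}

# GLS fixed effects and the weighted residual solve used by all BLUPs:
# beta = (X' V^-1 X)^-1 X' V^-1 y with V = K + delta I (scale-free),
# alpha = V^-1 (y - X beta)
gls_solve <- function(y, X, K, delta) {
  V <- K + diag(delta, nrow(K))
  Vi_y <- solve(V, y)
  Vi_X <- solve(V, X)
  beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  alpha <- solve(V, y - X %*% beta)
  list(beta = drop(beta), alpha = drop(alpha))
}
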