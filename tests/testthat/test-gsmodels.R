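test_that("rrBLUP closed form matches the hand example at fixed lambda", {
  # dosages (2, 0) center to the printed G = (1, -1)
  g <- geno_matrix(matrix(c(2, 0), ncol = 1,
                          dimnames = list(c("a", "b"), "M1")))
  fit <- fit_rrblup(g, c(a = 1, b = -1), lambda = 2)
  expect_equal(unname(fit$u), 0.5, tolerance = 1e-12)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-12)
})

test_that("rrBLUP at fixed lambda equals the penalized least squares oracle", {
  fx <- small_study(seed = 81, lines_per_pop = 10, n_markers = 60)
  g <- fx$geno
  y <- blup_line_means(fx$ph, "E1", "trait")[rownames(g$dosage)]
  lambda <- 3.7
  fit <- fit_rrblup(g, y, lambda = lambda)
  # oracle: augmented ridge regression with unpenalized intercept
  Gc <- sweep(g$dosage, 2, colMeans(g$dosage))
  p <- ncol(Gc)
  X_aug <- rbind(cbind(1, Gc), cbind(0, sqrt(lambda) * diag(p)))
  y_aug <- c(y, rep(0, p))
  coefs <- qr.solve(X_aug, y_aug)
  expect_lt(max(abs(fit$u - coefs[-1])), 1e-8)
  expect_lt(abs(fit$beta - coefs[1]), 1e-8)
})

test_that("rrBLUP degenerates gracefully", {
  fx <- small_study(seed = 81, lines_per_pop = 10, n_markers = 60)
  g <- fx$geno
  y0 <- stats::setNames(rep(2, nrow(g$dosage)), rownames(g$dosage))
  expect_warning(f0 <- fit_rrblup(g, y0), "constant")
  expect_true(all(f0$u == 0))
  y <- blup_line_means(fx$ph, "E1", "trait")[rownames(g$dosage)]
  fbig <- fit_rrblup(g, y, lambda = 1e10)
  expect_lt(max(abs(fbig$u)), 1e-5)
})

test_that("G-BLUP equals rrBLUP under the kinship / lambda mapping", {
  fx <- small_study(seed = 83, lines_per_pop = 10, n_markers = 80)
  g <- fx$geno
  ids <- rownames(g$dosage)
  train <- ids[1:20]; new <- ids[21:30]
  y <- blup_line_means(fx$ph, "E1", "trait")
  lambda <- 5
  g_train <- g[train, ]
  fit_rr <- fit_rrblup(g_train, y[train], lambda = lambda)
  # kinship from the training-centered dosages, shared scaling constant c
  centers <- colMeans(g_train$dosage)
  p <- colMeans(g_train$dosage) / 2
  c0 <- 2 * sum(p * (1 - p))
  Zt <- sweep(g_train$dosage, 2, centers)
  Zn <- sweep(g$dosage[new, , drop = FALSE], 2, centers)
  K <- tcrossprod(Zt) / c0
  rownames(K) <- colnames(K) <- train
  fit_gb <- fit_gblup(K, y[train], lambda = lambda / c0)
  K_cross <- Zn %*% t(Zt) / c0
  rownames(K_cross) <- new
  p_rr <- predict(fit_rr, genotypes_new = g[new, ])
  p_gb <- predict(fit_gb, kinship_cross = K_cross)
  expect_lt(max(abs(p_rr - p_gb)), 1e-6)
  # and on the training lines themselves
  p_rr_t <- predict(fit_rr, genotypes_new = g_train)
  p_gb_t <- predict(fit_gb, kinship_cross = K)
  expect_lt(max(abs(p_rr_t - p_gb_t)), 1e-6)
})

test_that("G-BLUP respects identity kinship and duplicated lines", {
  set.seed(9)
  n <- 12
  y <- stats::setNames(rnorm(n), paste0("L", 1:n))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  fit <- fit_gblup(K, y, lambda = 1)
  expect_gt(cor(fit$g_hat, y - mean(y)), 0.9999)
  # duplicated line -> equal breeding values
  fx <- small_study(seed = 85, lines_per_pop = 8, n_markers = 60)
  d <- fx$geno$dosage
  d <- rbind(d, dupL = d[1, ])
  g2 <- geno_matrix(d, c(fx$geno$populations, dupL = "Par1xPar2"))
  K2 <- compute_kinship(g2)
  y2 <- blup_line_means(fx$ph, "E1", "trait")
  y2 <- c(y2, dupL = unname(y2[rownames(d)[1]]))
  fit2 <- fit_gblup(K2, y2, lambda = 2)
  expect_equal(unname(fit2$g_hat[rownames(d)[1]]), unname(fit2$g_hat["dupL"]),
               tolerance = 1e-8)
  # non-PSD kinship rejected
  K3 <- K; K3[1, 2] <- K3[2, 1] <- 5
  expect_error(fit_gblup(K3, y), "positive semidefinite")
})

test_that("Bayesian Lasso is reproducible and shrinks pure noise", {
  fx <- small_study(seed = 87, lines_per_pop = 12, n_markers = 60)
  g <- fx$geno
  set.seed(1)
  y <- stats::setNames(rnorm(nrow(g$dosage)), rownames(g$dosage))
  f1 <- fit_bayeslasso(g, y, chain_length = 800, burn_in = 300, seed = 4)
  f2 <- fit_bayeslasso(g, y, chain_length = 800, burn_in = 300, seed = 4)
  expect_identical(f1$u, f2$u)
  # shrinkage relative to single-marker OLS on the same noise
  Gc <- sweep(g$dosage, 2, colMeans(g$dosage))
  ols <- abs(drop(crossprod(Gc, y - mean(y))) / colSums(Gc^2))
  expect_lt(max(abs(f1$u)), 0.5 * max(ols))
  expect_lt(mean(abs(f1$u)), 0.25 * mean(ols))
})

test_that("Bayesian Lasso recovers a single large-effect QTL", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(n_markers = 100, lines_per_pop = 20, n_qtl = 5,
                      seed = 300 + s)
    sim <- simulate_populations(cfg)
    g <- sim$genotypes
    qtl <- 37
    set.seed(s)
    y <- g$dosage[, qtl] * 2 + rnorm(nrow(g$dosage), 0, 0.5)
    names(y) <- rownames(g$dosage)
    fit <- fit_bayeslasso(g, y, chain_length = 1500, burn_in = 500, seed = s)
    # the causal marker (or a near-perfect LD proxy) tops the ranking
    top <- which.max(abs(fit$u))
    r2 <- suppressWarnings(ld_r2(g$dosage[, top], g$dosage[, qtl]))
    isTRUE(top == qtl || (!is.na(r2) && r2 > 0.8))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("all three models are equivariant to phenotype shifts", {
  fx <- small_study(seed = 89, lines_per_pop = 10, n_markers = 50)
  g <- fx$geno
  y <- blup_line_means(fx$ph, "E1", "trait")[rownames(g$dosage)]
  K <- compute_kinship(g)
  shift <- 100
  p_rr1 <- predict(fit_rrblup(g, y, lambda = 2), genotypes_new = g)
  p_rr2 <- predict(fit_rrblup(g, y + shift, lambda = 2), genotypes_new = g)
  expect_equal(unname(p_rr2 - p_rr1), rep(shift, length(y)), tolerance = 1e-6)
  p_gb1 <- predict(fit_gblup(K, y, lambda = 2), kinship_cross = K)
  p_gb2 <- predict(fit_gblup(K, y + shift, lambda = 2), kinship_cross = K)
  expect_equal(unname(p_gb2 - p_gb1), rep(shift, length(y)), tolerance = 1e-6)
  p_bl1 <- predict(fit_bayeslasso(g, y, chain_length = 600, burn_in = 200,
                                  seed = 2), genotypes_new = g)
  p_bl2 <- predict(fit_bayeslasso(g, y + shift, chain_length = 600,
                                  burn_in = 200, seed = 2), genotypes_new = g)
  expect_equal(unname(p_bl2 - p_bl1), rep(shift, length(y)), tolerance = 0.3)
})

test_that("structure fixed effects absorb population means", {
  fx <- small_study(seed = 91, lines_per_pop = 12, n_markers = 60)
  g <- fx$geno
  y <- blup_line_means(fx$ph, "E1", "trait")[rownames(g$dosage)]
  # inject strong population offsets
  offs <- c(Par1xPar2 = 0, Par2xPar3 = 5, Par1xPar3 = -5)
  y2 <- y + offs[g$populations[names(y)]]
  sd_ <- structure_design(g$populations)
  fit <- fit_rrblup(g, y2, structure = sd_, lambda = 10)
  expect_equal(unname(fit$beta["Par2xPar3"] - fit$beta["Par1xPar2"]), 5,
               tolerance = 0.8)
  # a new line at the training marker means predicts its population effect
  centers <- matrix(round(fit$centers), nrow = 1,
                    dimnames = list("newL", names(fit$centers)))
  # prediction machinery: marker mismatch is refused
  expect_error(predict(fit, genotypes_new = g[, 1:10]), "markers")
})

test_that("predicting the training set reproduces the fitted values", {
  fx <- small_study(seed = 93, lines_per_pop = 10, n_markers = 50)
  g <- fx$geno
  y <- blup_line_means(fx$ph, "E1", "trait")[rownames(g$dosage)]
  fit <- fit_rrblup(g, y)
  pred <- predict(fit, genotypes_new = g)
  Gc <- sweep(g$dosage, 2, fit$centers)
  expect_equal(unname(pred), unname(fit$beta[1] + drop(Gc %*% fit$u)),
               tolerance = 1e-10)
  # a line sitting at the training marker means predicts the intercept
  mid <- predict(fit, genotypes_new = geno_matrix(
    matrix(1, 1, ncol(Gc), dimnames = list("mid", colnames(Gc)))))
  expect_equal(unname(mid),
               unname(fit$beta[1] + drop((1 - fit$centers) %*% fit$u)))
})
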