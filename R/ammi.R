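#' AMMI analysis of a genotype x environment table
#'
#' Additive Main effects and Multiplicative Interaction: the cell-mean matrix
#' is decomposed into grand mean, genotype and environment main effects (by
#' row/column centering) plus a singular value decomposition of the
#' double-centered interaction matrix,
#' `Y_ij = m + G_i + L_j + sum_n (u_in sqrt(l_n)) (v_jn sqrt(l_n)) + d_ij`,
#' with `u`, `v` unit-norm axis scores and `l_n` the singular values of the
#' interaction. The number of retained axes is chosen by iterating the F_R
#' residual test from n = 0, adding an axis while the residual interaction is
#' significant at `alpha`. Axis signs follow a deterministic convention: the
#' score of the lexicographically first environment is nonnegative on every
#' axis.
#'
#' @param cell_means complete genotype x environment matrix of entry means
#'   (averaged over replicates).
#' @param ms_error plot-level error mean square from the replicated ANOVA.
#' @param df_error its degrees of freedom.
#' @param n_reps number of replicates behind each cell mean.
#' @param alpha significance level for the F_R axis test (default 0.05).
#' @param max_axes upper bound on retained axes (default `min(g, e) - 1`).
#' @return object of class `ammi_fit` with elements `grand_mean`,
#'   `genotype_effects`, `environment_effects`, `singular_values`,
#'   `genotype_scores`, `environment_scores` (unit-norm columns),
#'   `retained_axes`, `pct_gei_explained`, `residual`, `gei_ss`, and the F_R
#'   test table `axis_tests`.
#' @export
ammi_fit <- function(cell_means, ms_error, df_error, n_reps, alpha = 0.05,
                     max_axes = NULL) {
  Y <- as.matrix(cell_means)
  if (nrow(Y) < 2 || ncol(Y) < 2) stop2("need >= 2 genotypes and >= 2 environments")
  if (anyNA(Y)) stop2("cell-mean matrix must be complete (no imputation)")
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("G%03d", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("E%d", seq_len(ncol(Y)))
  g <- nrow(Y); e <- ncol(Y)
  m <- mean(Y)
  G <- rowMeans(Y) - m
  L <- colMeans(Y) - m
  D <- Y - outer(G + m, L, `+`)          # double-centered interaction
  sv <- svd(D)
  n_ax <- min(g - 1, e - 1)
  l <- sv$d[seq_len(n_ax)]^2             # axis SS (squared singular values)
  U <- sv$u[, seq_len(n_ax), drop = FALSE]
  V <- sv$v[, seq_len(n_ax), drop = FALSE]
  # sign convention: lexicographically first environment nonnegative
  ref <- which.min(rank(colnames(Y), ties.method = "first"))
  for (n in seq_len(n_ax)) {
    if (V[ref, n] < 0) { V[, n] <- -V[, n]; U[, n] <- -U[, n] }
  }
  rownames(U) <- rownames(Y); rownames(V) <- colnames(Y)
  gei_ss <- sum(D^2)
  pct <- if (gei_ss > 0) 100 * l / gei_ss else rep(0, n_ax)
  # axis retention by the F_R residual test
  max_axes <- min(max_axes %||% n_ax, n_ax)
  retained <- 0L
  tests <- list()
  for (n in 0:max_axes) {
    tst <- f_r_test(gei_ss, if (n > 0) l[seq_len(n)] else numeric(0),
                    n_geno = g, n_env = e, ms_error = ms_error,
                    df_error = df_error, n_reps = n_reps)
    tests[[n + 1]] <- data.frame(axes_fitted = n, F = tst$F, df1 = tst$df1,
                                 df2 = tst$df2, p = tst$p)
    if (is.na(tst$p) || tst$p >= alpha) break
    retained <- n + 1L
  }
  retained <- min(retained, max_axes)
  recon <- outer(G + m, L, `+`)
  if (retained > 0) {
    Ur <- U[, seq_len(retained), drop = FALSE]
    Vr <- V[, seq_len(retained), drop = FALSE]
    recon <- recon + Ur %*% diag(sqrt(l[seq_len(retained)]), retained) %*% t(Vr)
  }
  structure(list(grand_mean = m,
                 genotype_effects = G,
                 environment_effects = L,
                 singular_values = sqrt(l),
                 axis_ss = l,
                 genotype_scores = U,
                 environment_scores = V,
                 retained_axes = retained,
                 pct_gei_explained = pct,
                 residual = Y - recon,
                 gei_ss = gei_ss,
                 cell_means = Y,
                 n_reps = n_reps, ms_error = ms_error, df_error = df_error,
                 axis_tests = do.call(rbind, tests)),
            class = "ammi_fit")
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat(sprintf("<ammi_fit> %d genotypes x %d environments, %d axis(es) retained\n",
              nrow(x$genotype_scores), nrow(x$environment_scores),
              x$retained_axes))
  cat("  %% GEI explained:",
      paste(sprintf("%.1f", x$pct_gei_explained), collapse = ", "), "\n")
  invisible(x)
}

#' F_R test of the AMMI residual
#'
#' Cornelius-style residual test: after fitting the first `n` interaction
#' axes, the residual interaction sum of squares (on the cell-mean scale,
#' multiplied by `n_reps` to return to the plot scale) divided by the residual
#' degrees of freedom `(g - 1 - n)(e - 1 - n)` is referred to the plot-level
#' error mean square as an F statistic. A significant result means at least
#' one more axis is needed.
#'
#' @param gei_ss interaction sum of squares of the cell means.
#' @param axis_ss sums of squares of the leading axes already fitted (possibly
#'   empty).
#' @param n_geno,n_env numbers of genotypes and environments.
#' @param ms_error,df_error plot-level error mean square and its df.
#' @param n_reps replicates per cell mean.
#' @return list with `F`, `df1`, `df2`, `p` (`p = 1` when the residual SS is
#'   zero; `NA` when no residual df remain).
#' @export
f_r_test <- function(gei_ss, axis_ss = numeric(0), n_geno, n_env,
                     ms_error, df_error, n_reps) {
  if (df_error <= 0) stop2("`df_error` must be positive")
  n <- length(axis_ss)
  df_r <- (n_geno - 1 - n) * (n_env - 1 - n)
  if (df_r <= 0) return(list(F = NA_real_, df1 = 0, df2 = df_error, p = NA_real_))
  res_ss <- gei_ss - sum(axis_ss)
  if (res_ss <= 1e-12 * max(gei_ss, 1)) res_ss <- max(res_ss, 0)
  f <- (res_ss * n_reps / df_r) / ms_error
  p <- if (res_ss == 0) 1 else stats::pf(f, df_r, df_error, lower.tail = FALSE)
  list(F = f, df1 = df_r, df2 = df_error, p = p)
}

#' Nominal values along an interaction axis
#'
#' The nominal value of entry `i` in environment `j` excludes the environment
#' main effect: `m + G_i + (u_in sqrt(l_n)) (v_jn sqrt(l_n))`. Plotted against
#' the environment score, each genotype is a straight line whose slope is its
#' own axis score — the classic AMMI adaptation plot.
#'
#' @param fit an `ammi_fit`.
#' @param axis axis index (must be retained).
#' @return data.frame with columns `genotype`, `environment`, `env_score`
#'   (`v_jn sqrt(l_n)`), `nominal`.
#' @export
nominal_yields <- function(fit, axis = 1) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (axis > fit$retained_axes)
    stop2("axis ", axis, " not retained (", fit$retained_axes, " retained)")
  sl <- fit$singular_values[axis]
  gs <- fit$genotype_scores[, axis] * sqrt(sl)
  es <- fit$environment_scores[, axis] * sqrt(sl)
  out <- expand.grid(genotype = names(fit$genotype_effects),
                     environment = names(fit$environment_effects),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$env_score <- es[out$environment]
  out$nominal <- fit$grand_mean + fit$genotype_effects[out$genotype] +
    gs[out$genotype] * es[out$environment]
  rownames(out) <- NULL
  out
}

#' Select top entries per environment and overall
#'
#' Entries are ranked by AMMI-modelled values (retained axes) within each
#' environment, and by their main effect across environments; the union of
#' the per-environment top `per_environment`, the overall top `overall`, and
#' any `references` is returned (set semantics).
#'
#' @param fit an `ammi_fit`.
#' @param per_environment entries to take per environment.
#' @param overall entries to take on the across-environment mean.
#' @param references entry ids always included.
#' @return character vector of entry ids.
#' @export
select_top_entries <- function(fit, per_environment = 2, overall = 2,
                               references = character(0)) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (per_environment < 0 || overall < 0) stop2("counts must be >= 0")
  modelled <- fit$cell_means - fit$residual
  picks <- character(0)
  if (per_environment > 0)
    for (j in seq_len(ncol(modelled)))
      picks <- c(picks, rownames(modelled)[order(modelled[, j],
                                                 decreasing = TRUE)][seq_len(per_environment)])
  if (overall > 0) {
    ord <- names(sort(fit$genotype_effects, decreasing = TRUE))
    picks <- c(picks, ord[seq_len(overall)])
  }
  unique(c(picks, references))
}
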