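#' Variance components, heritability and BLUP for balanced RCB trials
#'
#' Variance components are estimated by the method of moments from the
#' expected mean squares (EMS) of the balanced ANOVA; for balanced data this
#' equals the REML solution, which is verified against lme4 in the test suite
#' rather than shipped. Negative component estimates are clamped to zero and
#' flagged.
#'
#' @name quantgen
NULL

new_vc <- function(S_G2 = NA_real_, S_GE2 = NA_real_, S_e2 = NA_real_,
                   n_reps, n_envs, f_tests = NULL, clamped = character(0),
                   extra = list()) {
  structure(c(list(S_G2 = S_G2, S_GE2 = S_GE2, S_e2 = S_e2,
                   n_reps = n_reps, n_envs = n_envs,
                   f_tests = f_tests, clamped = clamped), extra),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n")
  for (nm in setdiff(names(x), c("f_tests", "clamped", "n_reps", "n_envs")))
    if (is.numeric(x[[nm]]) && !is.na(x[[nm]]))
      cat(sprintf("  %-8s %.5g\n", nm, x[[nm]]))
  if (length(x$clamped))
    cat("  clamped at 0:", paste(x$clamped, collapse = ", "), "\n")
  invisible(x)
}

clamp0 <- function(x, name, clamped) {
  if (is.na(x)) return(list(x = x, clamped = clamped))
  if (x < 0) list(x = 0, clamped = c(clamped, name)) else list(x = x, clamped = clamped)
}

check_balanced <- function(ph, trait, envs = NULL) {
  if (!all(c("line", "environment", "block", trait) %in% names(ph)))
    stop2("phenotype table must have columns line, environment, block, ", trait)
  if (anyNA(ph[[trait]])) stop2("missing trait values; design must be balanced")
  tab <- table(ph$line, ph$environment, ph$block)
  if (length(unique(as.vector(tab))) != 1L || tab[1] != 1L)
    stop2("unbalanced design: every line x environment x block cell must occur exactly once")
  invisible(TRUE)
}

# mean squares from a sequential ANOVA on a balanced design
anova_ms <- function(formula, data) {
  a <- stats::anova(stats::lm(formula, data = data))
  ms <- a[["Mean Sq"]]; df <- a[["Df"]]; ss <- a[["Sum Sq"]]
  names(ms) <- names(df) <- names(ss) <- rownames(a)
  list(ms = ms, df = df, ss = ss)
}

# fetch an ANOVA line by its set of factor names, order-independent
term_key <- function(res, vars) {
  keys <- vapply(names(res$ms), function(nm)
    paste(sort(strsplit(nm, ":", fixed = TRUE)[[1]]), collapse = ":"),
    character(1))
  want <- paste(sort(vars), collapse = ":")
  hit <- names(res$ms)[keys == want]
  if (length(hit) != 1L) stop2("ANOVA term not found: ", want)
  hit
}

#' Single-environment variance components
#'
#' Within one environment of a balanced RCB trial, fits the genotype + block
#' ANOVA and returns `S_G2 = (MS_G - MS_e) / n` (n = blocks) and
#' `S_e2 = MS_e`, with the genotype F test (`MS_G / MS_e`). With
#' `per_population = TRUE` the analysis is repeated within each RIL
#' population, as used for the within-population genetic coefficient of
#' variation.
#'
#' @param ph long-format phenotype table.
#' @param environment environment id.
#' @param trait trait column name.
#' @param per_population analyse each population separately?
#' @return a `variance_components` object, or a named list of them.
#' @export
estimate_vc_single_env <- function(ph, environment, trait,
                                   per_population = FALSE) {
  sub <- ph[ph$environment == environment, , drop = FALSE]
  if (!nrow(sub)) stop2("no records for environment ", environment)
  if (per_population) {
    pops <- unique(sub$population)
    out <- lapply(pops, function(pp)
      estimate_vc_single_env(sub[sub$population == pp, , drop = FALSE],
                             environment, trait))
    names(out) <- pops
    return(out)
  }
  check_balanced(sub, trait)
  sub$line <- factor(sub$line); sub$block <- factor(sub$block)
  n <- nlevels(sub$block)
  res <- anova_ms(stats::as.formula(paste(trait, "~ block + line")), sub)
  ms_g <- res$ms[["line"]]; ms_e <- res$ms[["Residuals"]]
  clamped <- character(0)
  sg <- clamp0((ms_g - ms_e) / n, "S_G2", clamped)
  f <- ms_g / ms_e
  ft <- data.frame(term = "genotype", F = f,
                   df1 = res$df[["line"]], df2 = res$df[["Residuals"]],
                   p = stats::pf(f, res$df[["line"]], res$df[["Residuals"]],
                                 lower.tail = FALSE))
  new_vc(S_G2 = sg$x, S_e2 = ms_e, n_reps = n, n_envs = 1L,
         f_tests = ft, clamped = sg$clamped,
         extra = list(mean = mean(sub[[trait]])))
}

#' Multi-environment variance components
#'
#' Balanced across environments. Without the population factor, the random
#' model `Y = m + E + B(E) + G + GE + e` yields, from expected mean squares,
#' `S_GE2 = (MS_GE - MS_e) / r` and `S_G2 = (MS_G - MS_GE) / (r e)`. With
#' `with_population_factor = TRUE` the model
#' `Y = m + R + G(R) + E + B(E) + RE + G(R)E + e` is used instead, returning
#' the between-population (`S_R2`), within-population (`S_GR2`),
#' population-by-environment (`S_RE2`) and genotype-within-population-by-
#' environment (`S_GRE2`) components; the F test of `R` is a Satterthwaite
#' quasi-F. Each component's significance comes from the corresponding ANOVA
#' F ratio against its EMS error line.
#'
#' @param ph long-format phenotype table.
#' @param trait trait column name.
#' @param with_population_factor include the RIL-population factor?
#' @return `variance_components`.
#' @export
estimate_vc_multi_env <- function(ph, trait, with_population_factor = FALSE) {
  envs <- unique(ph$environment)
  if (length(envs) < 2) stop2("need at least 2 environments")
  check_balanced(ph, trait)
  d <- ph
  d$line <- factor(d$line); d$environment <- factor(d$environment)
  d$block <- factor(d$block); d$population <- factor(d$population)
  r <- nlevels(d$block); e <- nlevels(d$environment)
  clamped <- character(0)
  if (!with_population_factor) {
    res <- anova_ms(stats::as.formula(
      paste(trait, "~ environment + environment:block + line + line:environment")), d)
    ms_g <- res$ms[["line"]]
    ms_ge <- res$ms[[term_key(res, c("environment", "line"))]]
    ms_e <- res$ms[["Residuals"]]
    sge <- clamp0((ms_ge - ms_e) / r, "S_GE2", clamped)
    sg <- clamp0((ms_g - ms_ge) / (r * e), "S_G2", sge$clamped)
    f_g <- ms_g / ms_ge; f_ge <- ms_ge / ms_e
    ft <- data.frame(
      term = c("G", "GE"),
      F = c(f_g, f_ge),
      df1 = c(res$df[["line"]], res$df[[term_key(res, c("environment", "line"))]]),
      df2 = c(res$df[[term_key(res, c("environment", "line"))]], res$df[["Residuals"]]),
      p = c(stats::pf(f_g, res$df[["line"]], res$df[[term_key(res, c("environment", "line"))]],
                      lower.tail = FALSE),
            stats::pf(f_ge, res$df[[term_key(res, c("environment", "line"))]], res$df[["Residuals"]],
                      lower.tail = FALSE)))
    return(new_vc(S_G2 = sg$x, S_GE2 = sge$x, S_e2 = ms_e,
                  n_reps = r, n_envs = e, f_tests = ft, clamped = sg$clamped,
                  extra = list(mean = mean(d[[trait]]))))
  }
  # population-factor analysis; requires equal lines per population
  g_per_pop <- table(d$population[!duplicated(d$line)])
  if (length(unique(as.vector(g_per_pop))) != 1L)
    stop2("population-factor EMS analysis requires equal lines per population")
  g <- as.vector(g_per_pop)[1]
  k <- nlevels(d$population)
  res <- anova_ms(stats::as.formula(paste(
    trait,
    "~ population + line + environment + environment:block +",
    "population:environment + line:environment")), d)
  # with unique line ids, `line` after `population` carries G(R) df, and
  # `line:environment` after `population:environment` carries G(R)E df
  ms_r <- res$ms[["population"]]
  ms_gr <- res$ms[["line"]]
  ms_re <- res$ms[[term_key(res, c("population", "environment"))]]
  ms_gre <- res$ms[[term_key(res, c("environment", "line"))]]
  ms_e <- res$ms[["Residuals"]]
  s_gre <- clamp0((ms_gre - ms_e) / r, "S_GRE2", clamped)
  s_gr <- clamp0((ms_gr - ms_gre) / (r * e), "S_GR2", s_gre$clamped)
  s_re <- clamp0((ms_re - ms_gre) / (r * g), "S_RE2", s_gr$clamped)
  s_r <- clamp0((ms_r - ms_gr - ms_re + ms_gre) / (r * e * g), "S_R2",
                s_re$clamped)
  # Satterthwaite quasi-F for the population main effect
  num <- ms_r + ms_gre; den <- ms_gr + ms_re
  df_num <- num^2 / (ms_r^2 / res$df[["population"]] +
                       ms_gre^2 / res$df[[term_key(res, c("environment", "line"))]])
  df_den <- den^2 / (ms_gr^2 / res$df[["line"]] +
                       ms_re^2 / res$df[[term_key(res, c("population", "environment"))]])
  f <- c(R = num / den,
         GR = ms_gr / ms_gre,
         RE = ms_re / ms_gre,
         GRE = ms_gre / ms_e)
  df1 <- c(df_num, res$df[["line"]], res$df[[term_key(res, c("population", "environment"))]],
           res$df[[term_key(res, c("environment", "line"))]])
  gre_df <- res$df[[term_key(res, c("environment", "line"))]]
  df2 <- c(df_den, gre_df, gre_df, res$df[["Residuals"]])
  ft <- data.frame(term = names(f), F = unname(f), df1 = df1, df2 = df2,
                   p = stats::pf(unname(f), df1, df2, lower.tail = FALSE))
  new_vc(S_e2 = ms_e, n_reps = r, n_envs = e, f_tests = ft,
         clamped = s_r$clamped,
         extra = list(S_R2 = s_r$x, S_GR2 = s_gr$x, S_RE2 = s_re$x,
                      S_GRE2 = s_gre$x, mean = mean(d[[trait]])))
}

#' Genetic coefficient of variation
#'
#' `CV_g = 100 * sqrt(S_G2) / m`, with `m` the trait mean; expresses
#' within-population genetic variation as a percentage of the mean.
#'
#' @param S_G2 genotypic variance component (>= 0).
#' @param mean trait mean (nonzero).
#' @return percent.
#' @export
cv_g <- function(S_G2, mean) {
  if (S_G2 < 0) stop2("`S_G2` must be >= 0")
  if (mean == 0) stop2("trait mean is zero; CV_g undefined")
  100 * sqrt(S_G2) / mean
}

#' Broad-sense heritability, single environment
#'
#' Genotype-mean-basis heritability `H2 = S_G2 / (S_G2 + S_e2 / n)` with `n`
#' replications.
#'
#' @param S_G2,S_e2 variance components (>= 0).
#' @param n_reps number of replications (>= 1).
#' @return value in `[0, 1]`.
#' @export
h2_single_env <- function(S_G2, S_e2, n_reps) {
  if (S_G2 < 0 || S_e2 < 0) stop2("components must be >= 0")
  if (n_reps < 1) stop2("`n_reps` must be >= 1")
  den <- S_G2 + S_e2 / n_reps
  if (den == 0) stop2("all variance components are zero; H2 undefined")
  S_G2 / den
}

#' Broad-sense heritability across environments
#'
#' `H2 = S_G2 / (S_G2 + S_GE2 / e + S_e2 / (e n))` with `e` environments and
#' `n` replications; reduces to [h2_single_env()] when `e = 1` and
#' `S_GE2 = 0`.
#'
#' @param S_G2,S_GE2,S_e2 variance components (>= 0).
#' @param n_envs,n_reps numbers of environments and replications.
#' @return value in `[0, 1]`.
#' @export
h2_multi_env <- function(S_G2, S_GE2, S_e2, n_envs, n_reps) {
  if (S_G2 < 0 || S_GE2 < 0 || S_e2 < 0) stop2("components must be >= 0")
  if (n_envs < 1 || n_reps < 1) stop2("`n_envs` and `n_reps` must be >= 1")
  den <- S_G2 + S_GE2 / n_envs + S_e2 / (n_envs * n_reps)
  if (den == 0) stop2("all variance components are zero; H2 undefined")
  S_G2 / den
}

#' Genetic correlation between two environments
#'
#' `r_g = r / (H1 * H2)` where `r` is the phenotypic correlation of genotype
#' values across the pair of environments and `H1`, `H2` are the square roots
#' of the per-environment broad-sense heritabilities. Estimation noise can
#' push `|r_g|` beyond 1; the value is returned as-is with attribute
#' `flagged = TRUE` in that case.
#'
#' @param r_pheno phenotypic correlation.
#' @param H_env1,H_env2 square roots of heritability, in (0, 1].
#' @return r_g (attribute `flagged` when `|r_g| > 1`).
#' @export
genetic_correlation <- function(r_pheno, H_env1, H_env2) {
  if (H_env1 <= 0 || H_env2 <= 0) stop2("H values must be > 0")
  if (H_env1 > 1 || H_env2 > 1) stop2("H values must be <= 1")
  rg <- r_pheno / (H_env1 * H_env2)
  if (abs(rg) > 1) attr(rg, "flagged") <- TRUE
  rg
}

#' Shrunken (BLUP) line means for one environment
#'
#' For a balanced RCB trial the best linear unbiased prediction of a line's
#' genotypic value shrinks its raw mean toward the environment grand mean by
#' the heritability: `BLUP_i = m + H2 * (ybar_i - m)`, with `H2` from the
#' pooled-genotype single-environment components. These values are the
#' phenotypic inputs to all genomic selection modelling.
#'
#' @param ph long-format phenotype table.
#' @param environment environment id.
#' @param trait trait column name.
#' @return named numeric vector, one BLUP per line.
#' @export
blup_line_means <- function(ph, environment, trait) {
  vc <- estimate_vc_single_env(ph, environment, trait)
  sub <- ph[ph$environment == environment, , drop = FALSE]
  m <- mean(sub[[trait]])
  ybar <- tapply(sub[[trait]], sub$line, mean)
  H2 <- h2_single_env(vc$S_G2, vc$S_e2, vc$n_reps)
  out <- m + H2 * (ybar - m)
  stats::setNames(as.numeric(out), names(ybar))
}

#' Pearson correlations among traits
#'
#' Correlations (with two-sided t-test p-values) between trait columns of a
#' line x trait table, pooled or within each population. Constant columns
#' yield `NA` with a warning.
#'
#' @param line_values data.frame with a `line` column, optionally
#'   `population`, and numeric trait columns.
#' @param grouping `"pooled"` or `"population"`.
#' @return list (per group) of lists with elements `r` and `p` matrices.
#' @export
trait_correlations <- function(line_values, grouping = c("pooled", "population")) {
  grouping <- match.arg(grouping)
  traits <- names(line_values)[vapply(line_values, is.numeric, TRUE)]
  groups <- if (grouping == "pooled") list(pooled = line_values)
            else split(line_values, line_values$population)
  lapply(groups, function(dd) {
    if (nrow(dd) < 3) stop2("need at least 3 lines per group")
    X <- as.matrix(dd[, traits, drop = FALSE])
    const <- apply(X, 2, function(x) stats::sd(x) == 0)
    if (any(const))
      warning("constant trait(s): ", paste(traits[const], collapse = ", "),
              "; correlations undefined", call. = FALSE)
    r <- suppressWarnings(stats::cor(X))
    n <- nrow(X)
    t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
    diag(p) <- NA
    list(r = r, p = p, n = n)
  })
}

#' Pairwise comparison of population means (plumbing)
#'
#' Plain pairwise t-tests of population trait means on line means in one
#' environment; provided as a convenience, without multiple-comparison letter
#' displays.
#'
#' @param ph phenotype table; @param environment environment id;
#' @param trait trait column.
#' @return `pairwise.htest` from [stats::pairwise.t.test()].
#' @export
compare_populations <- function(ph, environment, trait) {
  sub <- ph[ph$environment == environment, ]
  lm_means <- stats::aggregate(sub[[trait]],
                               list(line = sub$line, population = sub$population),
                               mean)
  stats::pairwise.t.test(lm_means$x, lm_means$population,
                         p.adjust.method = "none")
}
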