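hand_rcb <- function() {
  # 2 lines x 3 blocks, one environment; hand-computed ANOVA:
  # SS_block = 4, SS_line = 24, SS_e = 0 -> S_G2 = 8, S_e2 = 0
  data.frame(line = rep(c("a", "b"), each = 3),
             population = "p1",
             environment = "E1",
             block = rep(c("B1", "B2", "B3"), 2),
             trait = c(1, 2, 3, 5, 6, 7))
}

test_that("single-environment components match hand-computed EMS algebra", {
  vc <- suppressWarnings(estimate_vc_single_env(hand_rcb(), "E1", "trait"))
  expect_equal(vc$S_G2, 8)
  expect_equal(vc$S_e2, 0)
  expect_equal(vc$n_reps, 3L)
})

test_that("pure-noise phenotypes give a near-zero genotypic component", {
  set.seed(42)
  ph <- expand.grid(line = sprintf("L%02d", 1:30), environment = "E1",
                    block = c("B1", "B2", "B3"), stringsAsFactors = FALSE)
  ph$population <- "p1"
  ph$trait <- rnorm(nrow(ph))
  vc <- estimate_vc_single_env(ph, "E1", "trait")
  expect_lt(vc$S_G2, 0.15 * vc$S_e2)
})

test_that("balanced ANOVA components equal the lme4 REML oracle", {
  fx <- small_study(seed = 55, gei_model = "iid", lines_per_pop = 25,
                    n_markers = 120)
  ph <- fx$ph
  # single environment
  vc1 <- estimate_vc_single_env(ph, "E2", "trait")
  lm1 <- suppressWarnings(lme4::lmer(trait ~ block + (1 | line),
                    data = ph[ph$environment == "E2", ], REML = TRUE))
  v <- as.data.frame(lme4::VarCorr(lm1))
  expect_equal(vc1$S_G2, v$vcov[v$grp == "line"], tolerance = 1e-4)
  expect_equal(vc1$S_e2, v$vcov[v$grp == "Residual"], tolerance = 1e-4)
  # multi-environment
  vc <- estimate_vc_multi_env(ph, "trait")
  lm2 <- suppressWarnings(
    lme4::lmer(trait ~ environment + environment:block + (1 | line) +
                 (1 | line:environment), data = ph, REML = TRUE))
  v2 <- as.data.frame(lme4::VarCorr(lm2))
  expect_equal(vc$S_G2, v2$vcov[v2$grp == "line"], tolerance = 1e-2)
  expect_equal(vc$S_GE2, v2$vcov[v2$grp == "line:environment"],
               tolerance = 1e-2)
  expect_equal(vc$S_e2, v2$vcov[v2$grp == "Residual"], tolerance = 1e-2)
})

test_that("multi-environment analysis flags null GEI and errors on one env", {
  fx <- small_study(seed = 61, gei_sd_ratio = 0, lines_per_pop = 15,
                    n_markers = 100)
  vc <- estimate_vc_multi_env(fx$ph, "trait")
  ge_p <- vc$f_tests$p[vc$f_tests$term == "GE"]
  expect_gt(ge_p, 0.01)
  expect_lt(vc$S_GE2, 0.25 * max(vc$S_G2, vc$S_e2))
  expect_error(estimate_vc_multi_env(fx$ph[fx$ph$environment == "E1", ],
                                     "trait"), "2 environments")
})

test_that("the population-factor decomposition splits between and within", {
  fx <- small_study(seed = 63, gei_model = "iid", lines_per_pop = 20)
  vc <- estimate_vc_multi_env(fx$ph, "trait", with_population_factor = TRUE)
  expect_true(all(c("S_R2", "S_GR2", "S_RE2", "S_GRE2") %in% names(vc)))
  expect_true(all(unlist(vc[c("S_R2", "S_GR2", "S_RE2", "S_GRE2")]) >= 0))
  # pooled within + between variation should be near the pooled-genotype sum
  pooled <- estimate_vc_multi_env(fx$ph, "trait")
  expect_lt(abs((vc$S_R2 + vc$S_GR2) - pooled$S_G2),
            0.5 * pooled$S_G2 + 0.05)
})

test_that("sums of squares partition exactly on balanced designs", {
  fx <- small_study(seed = 65, lines_per_pop = 10, n_markers = 80)
  ph <- fx$ph
  a <- stats::anova(stats::lm(
    trait ~ environment + environment:block + line + line:environment,
    data = transform(ph, line = factor(line), environment = factor(environment),
                     block = factor(block))))
  total <- sum((ph$trait - mean(ph$trait))^2)
  expect_equal(sum(a[["Sum Sq"]]), total, tolerance = 1e-10)
})

test_that("CV_g and heritability formulas follow the printed arithmetic", {
  expect_equal(cv_g(0, 5), 0)
  expect_equal(cv_g(1, 10), 10)
  expect_equal(cv_g(4, 2), cv_g(16, 4))     # scale invariance
  expect_error(cv_g(1, 0), "zero")
  expect_equal(h2_single_env(1, 0, 3), 1)
  expect_equal(h2_single_env(1, 2, 3), 0.6)
  expect_gt(h2_single_env(1, 2, 5), h2_single_env(1, 2, 3))
  expect_equal(h2_multi_env(1, 0, 0, 3, 3), 1)
  expect_equal(h2_multi_env(2, 3, 6, 3, 3), 0.54545, tolerance = 1e-4)
  expect_equal(h2_multi_env(1, 0, 2, 1, 3), h2_single_env(1, 2, 3))
  expect_error(h2_single_env(0, 0, 3), "undefined")
})

test_that("genetic correlation rescales by the heritability roots", {
  expect_equal(genetic_correlation(0.3, 1, 1), 0.3)
  expect_equal(genetic_correlation(0.3, 0.8, 0.75), 0.5)
  expect_equal(genetic_correlation(0, 0.5, 0.9), 0)
  big <- genetic_correlation(0.9, 0.7, 0.7)
  expect_true(isTRUE(attr(big, "flagged")))
  expect_error(genetic_correlation(0.3, 0, 0.5), "> 0")
})

test_that("BLUP line means shrink raw means toward the grand mean by H2", {
  fx <- small_study(seed = 67)
  ph <- fx$ph
  b <- blup_line_means(ph, "E1", "trait")
  sub <- ph[ph$environment == "E1", ]
  raw <- tapply(sub$trait, sub$line, mean)
  expect_lte(stats::var(b), stats::var(as.numeric(raw)))
  vc <- estimate_vc_single_env(ph, "E1", "trait")
  H2 <- h2_single_env(vc$S_G2, vc$S_e2, vc$n_reps)
  m <- mean(sub$trait)
  expect_equal(unname(b), unname(m + H2 * (as.numeric(raw[names(b)]) - m)))
  # noiseless data: BLUP equals the line mean
  nl <- hand_rcb()
  nl$trait <- rep(c(0, 10), each = 3)     # no block or error variance
  expect_equal(unname(suppressWarnings(blup_line_means(nl, "E1", "trait"))),
               c(0, 10))
})

test_that("trait correlations behave at the trivial and null limits", {
  set.seed(7)
  lv <- data.frame(line = sprintf("L%03d", 1:300),
                   population = rep(c("p1", "p2", "p3"), each = 100),
                   t1 = rnorm(300))
  lv$t2 <- -lv$t1
  cc <- trait_correlations(lv[, c("line", "t1", "t2")])$pooled
  expect_equal(cc$r["t1", "t1"], 1)
  expect_equal(cc$r["t1", "t2"], -1)
  # independent traits: |r| < 0.2 in >= 95% of seeds at n = 300
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    abs(cor(rnorm(300), rnorm(300))) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # per-population grouping returns one matrix per population
  byp <- trait_correlations(lv, grouping = "population")
  expect_named(byp, c("p1", "p2", "p3"))
  lv$t3 <- 1
  expect_warning(trait_correlations(lv[, c("line", "t1", "t3")]), "constant")
})
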