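test_that("stratified folds are proportional partitions", {
  pops <- stats::setNames(rep(c("A", "B", "C"), c(102, 100, 104)),
                          sprintf("L%03d", 1:306))
  for (s in 1:5) {
    fold <- stratified_kfold(pops, 10, seed = s)
    expect_identical(sort(names(fold)), sort(names(pops)))
    expect_true(all(fold %in% 1:10))
    counts <- table(pops, fold)
    expect_true(all(counts >= 10 & counts <= 11))
  }
  # determinism
  expect_identical(stratified_kfold(pops, 10, seed = 3),
                   stratified_kfold(pops, 10, seed = 3))
  # leave-one-out per stratum at k = population size
  popsm <- stats::setNames(rep(c("A", "B"), each = 5), paste0("l", 1:10))
  lo <- stratified_kfold(popsm, 5, seed = 1)
  expect_true(all(table(popsm, lo) == 1))
  expect_error(stratified_kfold(popsm, 6, seed = 1), "smaller than k")
})

test_that("predictive ability averages within-population correlations", {
  obs <- stats::setNames(c(1:6, 1:6), c(paste0("a", 1:6), paste0("b", 1:6)))
  pops <- stats::setNames(rep(c("A", "B"), each = 6), names(obs))
  expect_equal(as.numeric(predictive_ability(obs, obs, pops)), 1)
  # one perfect, one perfectly inverted -> mean 0
  pred <- obs
  pred[7:12] <- -obs[7:12]
  r <- predictive_ability(obs, pred, pops)
  expect_equal(as.numeric(r), 0)
  expect_equal(unname(attr(r, "per_population")), c(1, -1))
  # per-population offsets are irrelevant
  pred2 <- obs; pred2[1:6] <- obs[1:6] + 50
  expect_equal(as.numeric(predictive_ability(obs, pred2, pops)), 1)
  # constant population flagged and excluded
  pred3 <- obs; pred3[7:12] <- 3
  expect_warning(r3 <- predictive_ability(obs, pred3, pops), "excluded")
  expect_equal(as.numeric(r3), 1)
})

test_that("run_cv is deterministic and near zero without heritable signal", {
  fx <- small_study(seed = 103, lines_per_pop = 12, n_markers = 60)
  g <- fx$geno
  y <- blup_line_means(fx$ph, "E1", "trait")[rownames(g$dosage)]
  r1 <- run_cv(gs_model("rrblup"), g, y, k = 4, repetitions = 2, seed = 7)
  r2 <- run_cv(gs_model("rrblup"), g, y, k = 4, repetitions = 2, seed = 7)
  expect_identical(r1$per_repetition_per_population_r,
                   r2$per_repetition_per_population_r)
  expect_equal(r1$n_repetitions, 2L)
  # null phenotype at 300 lines: |r_Ab| < 0.1
  fx300 <- small_study(seed = 105, lines_per_pop = 100, n_markers = 200,
                       n_qtl = 20)
  g300 <- fx300$geno
  set.seed(11)
  y0 <- stats::setNames(rnorm(300), rownames(g300$dosage))
  r0 <- run_cv(gs_model("rrblup"), g300, y0, k = 10, repetitions = 3,
               seed = 13)
  expect_lt(abs(r0$predictive_ability), 0.1)
})

test_that("averaging over repetitions stabilizes the estimate", {
  fx <- small_study(seed = 107, lines_per_pop = 15, n_markers = 80)
  g <- fx$geno
  y <- blup_line_means(fx$ph, "E1", "trait")[rownames(g$dosage)]
  one <- vapply(1:8, function(s)
    run_cv(gs_model("rrblup"), g, y, k = 5, repetitions = 1,
           seed = s)$predictive_ability, numeric(1))
  five <- vapply(1:8, function(s)
    run_cv(gs_model("rrblup"), g, y, k = 5, repetitions = 5,
           seed = 100 + s)$predictive_ability, numeric(1))
  expect_lt(stats::sd(five), stats::sd(one))
})

test_that("a duplicated validation environment reproduces the intra-environment CV", {
  fx <- small_study(seed = 109, lines_per_pop = 12, n_markers = 60)
  g <- fx$geno
  blups <- env_blups(fx)
  dup <- list(E1 = blups$E1, E1copy = blups$E1)
  inter <- inter_environment_cv(gs_model("rrblup"), g, dup, train_env = "E1",
                                k = 4, repetitions = 2, seed = 5,
                                validation_envs = "E1copy")
  intra <- run_cv(gs_model("rrblup"), g, blups$E1, k = 4, repetitions = 2,
                  seed = 5)
  expect_equal(inter$E1copy$predictive_ability, intra$predictive_ability,
               tolerance = 1e-12)
})

test_that("GEI degrades inter-environment transfer, zero GEI does not", {
  # without GEI the two estimates agree within 0.05
  fx0 <- small_study(seed = 111, gei_sd_ratio = 0, h2 = 0.7,
                     lines_per_pop = 40, n_markers = 150, n_qtl = 40)
  blups0 <- env_blups(fx0)
  intra0 <- run_cv(gs_model("rrblup"), fx0$geno, blups0$E1, k = 5,
                   repetitions = 3, seed = 3)
  inter0 <- inter_environment_cv(gs_model("rrblup"), fx0$geno, blups0,
                                 train_env = "E1", k = 5, repetitions = 3,
                                 seed = 3)
  gap0 <- intra0$predictive_ability -
    mean(vapply(inter0, `[[`, numeric(1), "predictive_ability"))
  expect_lt(abs(gap0), 0.05)
  # with strong GEI the inter-environment ability drops in most seeds
  drops <- vapply(1:4, function(s) {
    fx1 <- small_study(seed = 120 + s, gei_sd_ratio = 2, h2 = 0.6,
                       lines_per_pop = 25, n_markers = 100, n_qtl = 30)
    blups1 <- env_blups(fx1)
    intra <- run_cv(gs_model("rrblup"), fx1$geno, blups1$E1, k = 5,
                    repetitions = 2, seed = s)
    inter <- inter_environment_cv(gs_model("rrblup"), fx1$geno, blups1,
                                  train_env = "E1", k = 5, repetitions = 2,
                                  seed = s)
    intra$predictive_ability >
      mean(vapply(inter, `[[`, numeric(1), "predictive_ability"))
  }, logical(1))
  expect_gte(mean(drops), 0.75)
})

test_that("inter-population prediction favours populations sharing a parent", {
  gaps <- vapply(1:6, function(s) {
    cfg <- sim_config(n_parents = 4, n_markers = 250, lines_per_pop = 50,
                      n_qtl = 50, h2_per_env = 0.85, gei_sd_ratio = 0,
                      crosses = list(c(1L, 2L), c(1L, 3L), c(3L, 4L)),
                      seed = 130 + s)
    sim <- simulate_populations(cfg)
    tm <- make_trait_model(sim$genotypes, cfg)
    ph <- simulate_phenotypes(sim$genotypes, tm, cfg)
    blups <- list(E1 = blup_line_means(ph, "E1", "trait"))
    res <- inter_population_prediction(gs_model("rrblup"), sim$genotypes,
                                       blups, train_pop = "Par1xPar2",
                                       train_env = "E1",
                                       validation_scope = "same_env",
                                       seed = s)
    r <- res$per_repetition_per_population_r[1, ]
    r[["Par1xPar3"]] - r[["Par3xPar4"]]     # shares Par1 vs shares nothing
  }, numeric(1))
  expect_gt(mean(gaps), 0)                  # directional, averaged over seeds
})

test_that("inter-population scenarios label and average correctly", {
  fx <- small_study(seed = 141, lines_per_pop = 12, n_markers = 60)
  blups <- env_blups(fx)
  same <- inter_population_prediction(gs_model("rrblup"), fx$geno, blups,
                                      train_pop = "Par1xPar2",
                                      train_env = "E1",
                                      validation_scope = "same_env", seed = 1)
  expect_identical(same$scenario, "intra_env_inter_pop")
  other <- inter_population_prediction(gs_model("rrblup"), fx$geno, blups,
                                       train_pop = "Par1xPar2",
                                       train_env = "E1",
                                       validation_scope = "other_envs",
                                       seed = 1)
  expect_identical(other$scenario, "inter_env_inter_pop")
  # the reported r_Ab is the mean over validation populations of the
  # per-population values (themselves averaged over validation environments)
  expect_equal(other$predictive_ability,
               mean(rowMeans(other$per_environment_r)), tolerance = 1e-12)
  expect_error(inter_population_prediction(gs_model("rrblup"), fx$geno, blups,
                                           train_pop = "nope",
                                           train_env = "E1"), "population")
})

test_that("RMSD configuration choice follows the printed arithmetic", {
  tab <- expand.grid(model = c("m1", "m2"), threshold = c(0.01, 0.05),
                     trait = c("t1", "t2"), stringsAsFactors = FALSE)
  tab$pa <- c(0.50, 0.48, 0.46, 0.50,   # t1
              0.60, 0.56, 0.58, 0.60)   # t2
  rk <- rmsd_model_selection(tab)
  # m1@0.01: penalties (0, 0) -> rmsd 0, rank 1
  expect_equal(rk$rmsd[1], 0)
  expect_identical(rk$model[1], "m1")
  expect_equal(rk$threshold[1], 0.01)
  # m2@0.01: penalties (0.02, 0.04) -> 0.03162
  row <- rk[rk$model == "m2" & rk$threshold == 0.01, ]
  expect_equal(row$rmsd, sqrt(mean(c(0.02, 0.04)^2)), tolerance = 1e-12)
  expect_equal(round(row$rmsd, 5), 0.03162)
  # invariant to trait ordering
  rk2 <- rmsd_model_selection(tab[order(tab$trait, decreasing = TRUE), ])
  expect_equal(rk$rmsd, rk2$rmsd)
  expect_error(rmsd_model_selection(tab[-1, ]), "grid")
})
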