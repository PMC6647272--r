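#' Genomic prediction model specification
#'
#' A lightweight recipe naming one of the three whole-genome regression
#' models and its options, used by the cross-validation drivers.
#'
#' @param kind `"rrblup"`, `"gblup"` or `"bayeslasso"`.
#' @param use_structure add the RIL-population incidence fixed effects?
#' @param ... extra arguments passed to the fitting function (e.g.
#'   `chain_length`, `burn_in`, `thin` for the Bayesian Lasso; `lambda`).
#' @return object of class `gs_model_spec`.
#' @export
gs_model <- function(kind = c("rrblup", "gblup", "bayeslasso"),
                     use_structure = FALSE, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, use_structure = use_structure,
                 args = list(...)), class = "gs_model_spec")
}

# fit a spec on training lines and predict validation lines
fit_and_predict <- function(spec, genotypes, y_train, train_ids, valid_ids,
                            kinship = NULL, seed = 1) {
  g <- as_geno(genotypes)
  struct_all <- if (spec$use_structure) structure_design(g$populations) else NULL
  if (spec$kind == "gblup") {
    K <- kinship %||% compute_kinship(g)
    fit <- do.call(fit_gblup,
                   c(list(kinship = K[train_ids, train_ids],
                          y = y_train[train_ids],
                          structure = struct_all), spec$args))
    pred <- predict(fit, kinship_cross = K[valid_ids, train_ids, drop = FALSE],
                    structure_new = struct_all)
  } else {
    g_train <- g[train_ids, ]
    fitter <- if (spec$kind == "rrblup") fit_rrblup else fit_bayeslasso
    args <- c(list(genotypes = g_train, y = y_train[train_ids],
                   structure = struct_all), spec$args)
    if (spec$kind == "bayeslasso" && is.null(args$seed)) args$seed <- seed
    fit <- do.call(fitter, args)
    pred <- predict(fit, genotypes_new = g[valid_ids, ],
                    structure_new = struct_all)
  }
  pred
}

#' Stratified k-fold assignment
#'
#' Lines are partitioned into `k` folds separately within each population
#' (stratum), so per-fold population counts differ by at most one from
#' proportionality. Deterministic given `seed`.
#'
#' @param populations named vector line -> population label.
#' @param k number of folds.
#' @param seed integer seed.
#' @return named integer vector of fold ids (1..k) per line.
#' @export
stratified_kfold <- function(populations, k, seed = 1) {
  stopifnot(!is.null(names(populations)), k >= 2)
  pops <- split(names(populations), as.character(populations))
  small <- names(pops)[vapply(pops, length, 1L) < k]
  if (length(small))
    stop2("population(s) smaller than k: ", paste(small, collapse = ", "))
  with_local_seed(seed, {
    fold <- integer(0)
    for (ids in pops) {
      ids <- sample(ids)
      f <- rep_len(seq_len(k), length(ids))
      fold <- c(fold, stats::setNames(f, ids))
    }
    fold[names(populations)]
  })
}

#' Predictive ability averaged over populations
#'
#' Pearson correlation between observed and predicted values computed within
#' each population, then averaged unweighted across populations — population
#' means differ, and pooling would inflate the correlation. A population with
#' a constant observed or predicted vector is flagged and excluded from the
#' mean with a warning.
#'
#' @param observed,predicted named numeric vectors over the same lines.
#' @param populations named vector line -> population label.
#' @return `r_Ab`, with attribute `per_population` (named vector of
#'   within-population correlations).
#' @export
predictive_ability <- function(observed, predicted, populations) {
  ids <- intersect(names(observed), names(predicted))
  if (!length(ids)) stop2("no common lines between observed and predicted")
  pops <- split(ids, as.character(populations[ids]))
  r_pop <- vapply(pops, function(px) {
    if (length(px) < 3) return(NA_real_)
    o <- observed[px]; p <- predicted[px]
    if (stats::sd(o) == 0 || stats::sd(p) == 0) return(NA_real_)
    stats::cor(o, p)
  }, numeric(1))
  if (anyNA(r_pop))
    warning("population(s) excluded from r_Ab (constant or too small): ",
            paste(names(r_pop)[is.na(r_pop)], collapse = ", "), call. = FALSE)
  r <- mean(r_pop, na.rm = TRUE)
  attr(r, "per_population") <- r_pop
  r
}

new_cv_result <- function(scenario, r_mat, k, seed, ...) {
  # r_mat: repetitions x populations matrix of within-population correlations
  per_rep <- rowMeans(r_mat, na.rm = TRUE)
  structure(list(scenario = scenario,
                 per_repetition_per_population_r = r_mat,
                 per_repetition_r = per_rep,
                 predictive_ability = mean(per_rep),
                 n_repetitions = nrow(r_mat), k_folds = k, seed = seed, ...),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result:%s> r_Ab = %.3f (%d reps, k = %s)\n",
              x$scenario, x$predictive_ability, x$n_repetitions,
              x$k_folds %||% "-"))
  invisible(x)
}

#' Repeated stratified cross-validation (intra-environment)
#'
#' The workhorse 10-fold x 50-repetition protocol: for each repetition, lines
#' are split into `k` population-stratified folds; each fold is predicted
#' from a model trained on the remaining lines; within-population
#' correlations between observed and out-of-fold predicted values are
#' averaged across populations (first) and repetitions (second) into the
#' predictive ability `r_Ab`. Per-repetition fold seeds are derived
#' deterministically from the master seed.
#'
#' @param spec a [gs_model()].
#' @param genotypes complete `geno_matrix`.
#' @param phenotypes named vector of line values (per-environment BLUPs).
#' @param k folds (default 10).
#' @param repetitions repetitions (default 50).
#' @param seed master seed.
#' @return `cv_result`.
#' @export
run_cv <- function(spec, genotypes, phenotypes, k = 10, repetitions = 50,
                   seed = 1) {
  g <- as_geno(genotypes)
  ids <- line_ids(g)
  if (!all(ids %in% names(phenotypes))) stop2("phenotypes must cover all lines")
  y <- phenotypes[ids]
  pops <- g$populations
  pop_levels <- sort(unique(pops))
  K <- if (spec$kind == "gblup") compute_kinship(g) else NULL
  r_mat <- matrix(NA_real_, nrow = repetitions, ncol = length(pop_levels),
                  dimnames = list(NULL, pop_levels))
  for (rep in seq_len(repetitions)) {
    rep_seed <- derive_seed(seed, paste0("cv_rep_", rep))
    fold <- stratified_kfold(pops, k, seed = rep_seed)
    pred <- stats::setNames(rep(NA_real_, length(ids)), ids)
    for (f in seq_len(k)) {
      valid <- ids[fold == f]
      train <- ids[fold != f]
      pred[valid] <- fit_and_predict(spec, g, y, train, valid, kinship = K,
                                     seed = derive_seed(rep_seed, f))
    }
    r <- predictive_ability(y, pred, pops)
    r_mat[rep, ] <- attr(r, "per_population")[pop_levels]
  }
  new_cv_result("intra_env_intra_pop", r_mat, k, seed,
                model = spec$kind)
}

#' Inter-environment cross-validation
#'
#' A model trained (under the same stratified CV protocol) on one
#' environment's line values is used to predict, for the held-out lines, the
#' line values observed in each *other* environment. Returns one `cv_result`
#' per validation environment.
#'
#' @param spec a [gs_model()].
#' @param genotypes complete `geno_matrix`.
#' @param phenotypes_by_env named list environment -> named line-value vector.
#' @param train_env training environment id.
#' @param k,repetitions,seed as in [run_cv()].
#' @param validation_envs environments to evaluate (default all others).
#' @return named list of `cv_result` (scenario `inter_env_intra_pop`).
#' @export
inter_environment_cv <- function(spec, genotypes, phenotypes_by_env,
                                 train_env, k = 10, repetitions = 50,
                                 seed = 1, validation_envs = NULL) {
  g <- as_geno(genotypes)
  if (!train_env %in% names(phenotypes_by_env))
    stop2("unknown training environment: ", train_env)
  envs <- validation_envs %||% setdiff(names(phenotypes_by_env), train_env)
  ids <- line_ids(g)
  y_train_env <- phenotypes_by_env[[train_env]][ids]
  pops <- g$populations
  pop_levels <- sort(unique(pops))
  K <- if (spec$kind == "gblup") compute_kinship(g) else NULL
  r_mats <- lapply(envs, function(e)
    matrix(NA_real_, repetitions, length(pop_levels),
           dimnames = list(NULL, pop_levels)))
  names(r_mats) <- envs
  for (rep in seq_len(repetitions)) {
    # same derivation as run_cv: identical folds for a given master seed, so
    # a duplicated validation environment reproduces the intra-environment CV
    rep_seed <- derive_seed(seed, paste0("cv_rep_", rep))
    fold <- stratified_kfold(pops, k, seed = rep_seed)
    pred <- stats::setNames(rep(NA_real_, length(ids)), ids)
    for (f in seq_len(k)) {
      valid <- ids[fold == f]
      train <- ids[fold != f]
      pred[valid] <- fit_and_predict(spec, g, y_train_env, train, valid,
                                     kinship = K,
                                     seed = derive_seed(rep_seed, f))
    }
    for (e in envs) {
      obs <- phenotypes_by_env[[e]][ids]
      r <- suppressWarnings(predictive_ability(obs, pred, pops))
      r_mats[[e]][rep, ] <- attr(r, "per_population")[pop_levels]
    }
  }
  out <- lapply(envs, function(e)
    new_cv_result("inter_env_intra_pop", r_mats[[e]], k, seed,
                  model = spec$kind, train_env = train_env,
                  validation_env = e))
  names(out) <- envs
  out
}

#' Inter-population prediction
#'
#' A model is trained on *all* lines of one RIL population (no
#' cross-validation inside the training population) and used to predict the
#' lines of the other populations. Correlations are computed within each
#' validation population and averaged across validation populations; with
#' `validation_scope = "other_envs"` the model trained on `train_env` values
#' is evaluated against each other environment's values and results are
#' additionally averaged across validation environments.
#'
#' @param spec a [gs_model()].
#' @param genotypes complete `geno_matrix`.
#' @param phenotypes_by_env named list environment -> named line-value vector.
#' @param train_pop training population label.
#' @param train_env training environment id.
#' @param validation_scope `"same_env"` or `"other_envs"`.
#' @param seed seed (only used by stochastic models).
#' @return `cv_result` (scenario `intra_env_inter_pop` or
#'   `inter_env_inter_pop`); per-population columns are the validation
#'   populations (averaged over validation environments for `other_envs`).
#' @export
inter_population_prediction <- function(spec, genotypes, phenotypes_by_env,
                                        train_pop, train_env,
                                        validation_scope = c("same_env",
                                                             "other_envs"),
                                        seed = 1) {
  validation_scope <- match.arg(validation_scope)
  g <- as_geno(genotypes)
  pops <- g$populations
  if (!train_pop %in% pops) stop2("unknown population: ", train_pop)
  if (!train_env %in% names(phenotypes_by_env))
    stop2("unknown environment: ", train_env)
  ids <- line_ids(g)
  train_ids <- ids[pops == train_pop]
  valid_pops <- setdiff(sort(unique(pops)), train_pop)
  valid_ids <- ids[pops %in% valid_pops]
  y_train <- phenotypes_by_env[[train_env]]
  K <- if (spec$kind == "gblup") compute_kinship(g) else NULL
  pred <- fit_and_predict(spec, g, y_train, train_ids, valid_ids, kinship = K,
                          seed = derive_seed(seed, "interpop"))
  envs <- if (validation_scope == "same_env") train_env
          else setdiff(names(phenotypes_by_env), train_env)
  r_env <- vapply(envs, function(e) {
    obs <- phenotypes_by_env[[e]][valid_ids]
    r <- suppressWarnings(predictive_ability(obs, pred, pops))
    attr(r, "per_population")[valid_pops]
  }, numeric(length(valid_pops)))
  r_env <- matrix(r_env, nrow = length(valid_pops),
                  dimnames = list(valid_pops, envs))
  r_pop <- rowMeans(r_env, na.rm = TRUE)   # average over validation envs
  scen <- if (validation_scope == "same_env") "intra_env_inter_pop"
          else "inter_env_inter_pop"
  new_cv_result(scen, matrix(r_pop, nrow = 1,
                             dimnames = list(NULL, valid_pops)),
                k = NA_integer_, seed = seed, model = spec$kind,
                train_pop = train_pop, train_env = train_env,
                per_environment_r = r_env)
}

#' RMSD-based model and configuration selection
#'
#' For each (model, missing-threshold) configuration, the root mean square
#' difference over traits between the best predictive ability achieved for
#' that trait by any configuration and this configuration's predictive
#' ability. The configuration minimizing RMSD (ties: higher mean predictive
#' ability, then lower missing threshold) is the study-wide choice.
#'
#' @param pa_table data.frame with columns `model`, `threshold`, `trait`,
#'   `pa`; must be complete over the model x threshold x trait grid.
#' @return data.frame of configurations with `rmsd` and `mean_pa`, sorted
#'   ascending by RMSD.
#' @export
rmsd_model_selection <- function(pa_table) {
  need <- c("model", "threshold", "trait", "pa")
  if (!all(need %in% names(pa_table))) stop2("pa_table needs columns ",
                                             paste(need, collapse = ", "))
  grid <- table(pa_table$model, pa_table$threshold, pa_table$trait)
  if (any(grid != 1)) stop2("pa_table must cover the full grid exactly once")
  best <- tapply(pa_table$pa, pa_table$trait, max)
  pa_table$penalty <- best[pa_table$trait] - pa_table$pa
  agg <- stats::aggregate(cbind(penalty2 = pa_table$penalty^2,
                                pa = pa_table$pa),
                          by = list(model = pa_table$model,
                                    threshold = pa_table$threshold),
                          FUN = mean)
  out <- data.frame(model = agg$model, threshold = agg$threshold,
                    rmsd = sqrt(agg$penalty2), mean_pa = agg$pa)
  out[order(out$rmsd, -out$mean_pa, out$threshold), , drop = FALSE]
}
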