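#' Pipeline configuration
#'
#' Validates and completes a configuration for [run_study()]. The defaults
#' mirror the study protocol at desk scale: five marker missing-data
#' thresholds, MAF 0.05, the three regression models, 10-fold stratified CV,
#' GS/PS gain settings (t_G = 0.5, t_P in {1, 2}, intensity ratio 1.46) and
#' an association-score threshold of 3. Either a `simdata` block (arguments
#' for [sim_config()]) or `paths` (genotype/phenotype files) must be given.
#'
#' @param config named list or path to a YAML file.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    simdata = list(),
    paths = NULL,
    trait = "trait",
    qc = list(missing_thresholds = c(0.01, 0.05, 0.10, 0.20, 0.30),
              min_maf = 0.05, impute = "mode"),
    models = c("rrblup", "gblup"),
    cv = list(k = 10, repetitions = 50),
    scenarios = c("intra_env_intra_pop", "inter_env_intra_pop",
                  "intra_env_inter_pop", "inter_env_inter_pop"),
    gains = list(t_G = 0.5, t_P = c(1, 2), intensity_ratio = 1.46,
                 selected_fraction_ps = 0.10),
    gwas = list(threshold = 3, n_pcs = 2),
    seed = 1,
    out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$paths) && is.null(cfg$simdata))
    stop2("config must provide `simdata` or `paths`")
  if (!length(cfg$models)) stop2("model grid must be non-empty")
  if (!length(cfg$qc$missing_thresholds)) stop2("threshold grid must be non-empty")
  if (is.unsorted(cfg$qc$missing_thresholds))
    stop2("missing thresholds must be sorted ascending")
  if (is.null(cfg$seed)) stop2("a master seed is required")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full study pipeline
#'
#' Orchestrates the complete replication on synthetic (or user-supplied)
#' data: data generation or loading, marker QC over the missing-threshold
#' grid, variance components and heritability, AMMI analysis of the
#' genotype x environment means, the model-grid cross-validation with RMSD
#' configuration choice, the four prediction scenarios, the GS-vs-PS gain
#' calculus, and the association scan. All randomness derives from the
#' single master seed through a documented hash, so two runs with the same
#' config are identical.
#'
#' @param config a [pipeline_config()], a plain list, or a YAML path.
#' @param verbose log stage progress? Default TRUE.
#' @return a results bundle (list) with one element per stage, plus a
#'   `manifest` (seeds, config hash, package version, stage log). When
#'   `config$out_dir` is set, tables are also written as CSV/JSON files.
#' @export
run_study <- function(config = list(), verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  t0 <- Sys.time()
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (verbose) message("[peagain] ", msg)
  }
  bundle <- list()

  # --- stage: data ---------------------------------------------------------
  if (!is.null(cfg$paths)) {
    if (!file.exists(cfg$paths$genotypes %||% ""))
      stop2("stage data: genotype path missing or not found")
    geno_raw <- read_genotypes(cfg$paths$genotypes,
                               populations = cfg$paths$populations)
    ph <- read_phenotypes(cfg$paths$phenotypes)
    map <- NULL
    say("loaded %d lines x %d markers from disk", nrow(geno_raw$dosage),
        ncol(geno_raw$dosage))
  } else {
    sim_args <- utils::modifyList(cfg$simdata,
                                  list(seed = derive_seed(cfg$seed, "simdata")))
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_populations(scfg)
    trait <- make_trait_model(sim$genotypes, scfg)
    ph <- simulate_phenotypes(sim$genotypes, trait, scfg)
    names(ph)[names(ph) == "trait"] <- cfg$trait
    geno_raw <- if (scfg$missing_rate > 0)
      mask_missing(sim$genotypes, scfg$missing_rate,
                   seed = derive_seed(cfg$seed, "mask")) else sim$genotypes
    map <- sim$map
    bundle$sim <- list(config = scfg, trait_model = trait)
    say("simulated %d lines x %d markers, %d populations",
        nrow(geno_raw$dosage), ncol(geno_raw$dosage),
        length(unique(geno_raw$populations)))
  }
  trait <- cfg$trait
  envs <- sort(unique(ph$environment))

  # --- stage: QC grid ------------------------------------------------------
  qc <- lapply(cfg$qc$missing_thresholds, function(th) {
    g1 <- filter_missing_rate(geno_raw, th)
    g2 <- filter_maf(g1, cfg$qc$min_maf)
    impute_missing(g2, method = cfg$qc$impute,
                   seed = derive_seed(cfg$seed, paste0("impute", th)))
  })
  names(qc) <- as.character(cfg$qc$missing_thresholds)
  bundle$qc <- data.frame(threshold = cfg$qc$missing_thresholds,
                          n_markers = vapply(qc, function(g) ncol(g$dosage), 1L))
  say("QC: %s markers kept over thresholds %s",
      paste(bundle$qc$n_markers, collapse = "/"),
      paste(cfg$qc$missing_thresholds, collapse = "/"))

  # --- stage: quantitative genetics ---------------------------------------
  vc_multi <- estimate_vc_multi_env(ph, trait)
  vc_pop <- estimate_vc_multi_env(ph, trait, with_population_factor = TRUE)
  per_env <- lapply(envs, function(e) {
    vc <- estimate_vc_single_env(ph, e, trait)
    list(vc = vc, H2 = h2_single_env(vc$S_G2, vc$S_e2, vc$n_reps),
         cv_g = cv_g(vc$S_G2, vc$mean))
  })
  names(per_env) <- envs
  H2_multi <- h2_multi_env(vc_multi$S_G2, vc_multi$S_GE2, vc_multi$S_e2,
                           vc_multi$n_envs, vc_multi$n_reps)
  blups <- lapply(envs, function(e) blup_line_means(ph, e, trait))
  names(blups) <- envs
  bundle$quantgen <- list(vc_multi = vc_multi, vc_population = vc_pop,
                          per_env = per_env, H2_multi = H2_multi,
                          blups = blups)
  say("variance components: S_G2 = %.3g, S_GE2 = %.3g, H2 = %.2f",
      vc_multi$S_G2, vc_multi$S_GE2, H2_multi)
  if (length(vc_multi$clamped))
    say("warning: clamped components: %s",
        paste(vc_multi$clamped, collapse = ", "))

  # --- stage: AMMI ---------------------------------------------------------
  cell <- tapply(ph[[trait]], list(ph$line, ph$environment), mean)
  err_ms <- mean(vapply(envs, function(e) {
    vc <- per_env[[e]]$vc; vc$S_e2
  }, numeric(1)))
  df_err <- length(envs) * (nlevels(factor(ph$line)) - 1) *
    (nlevels(factor(ph$block)) - 1)
  fit <- ammi_fit(cell, ms_error = err_ms, df_error = df_err,
                  n_reps = vc_multi$n_reps)
  bundle$ammi <- list(fit = fit,
                      nominal = if (fit$retained_axes >= 1)
                        nominal_yields(fit, 1) else NULL,
                      top = select_top_entries(fit))
  say("AMMI: %d axis(es) retained, PC1 explains %.1f%% of GEI",
      fit$retained_axes, fit$pct_gei_explained[1])

  # --- stage: model-grid CV + RMSD selection -------------------------------
  chosen_geno <- qc[[1]]
  y_env1 <- blups[[1]]
  pa_rows <- list()
  for (mod in cfg$models) {
    for (th in names(qc)) {
      spec <- gs_model(mod)
      res <- run_cv(spec, qc[[th]], y_env1, k = cfg$cv$k,
                    repetitions = cfg$cv$repetitions,
                    seed = derive_seed(cfg$seed, paste0("cv", mod, th)))
      pa_rows[[paste(mod, th)]] <- data.frame(model = mod,
                                              threshold = as.numeric(th),
                                              trait = trait,
                                              pa = res$predictive_ability)
    }
  }
  pa_table <- do.call(rbind, pa_rows)
  rownames(pa_table) <- NULL
  ranking <- rmsd_model_selection(pa_table)
  best <- ranking[1, ]
  say("model grid: best = %s at threshold %g (RMSD %.4f)",
      best$model, best$threshold, best$rmsd)
  bundle$model_grid <- list(pa_table = pa_table, ranking = ranking,
                            selected = best)

  # --- stage: prediction scenarios ----------------------------------------
  sel_spec <- gs_model(as.character(best$model))
  sel_geno <- qc[[as.character(best$threshold)]]
  scen <- list()
  if ("intra_env_intra_pop" %in% cfg$scenarios)
    scen$intra_env_intra_pop <- run_cv(sel_spec, sel_geno, y_env1,
                                       k = cfg$cv$k,
                                       repetitions = cfg$cv$repetitions,
                                       seed = derive_seed(cfg$seed, "sc1"))
  if ("inter_env_intra_pop" %in% cfg$scenarios && length(envs) >= 2)
    scen$inter_env_intra_pop <- inter_environment_cv(
      sel_spec, sel_geno, blups, train_env = envs[1], k = cfg$cv$k,
      repetitions = cfg$cv$repetitions, seed = derive_seed(cfg$seed, "sc2"))
  pops <- unique(sel_geno$populations)
  if ("intra_env_inter_pop" %in% cfg$scenarios && length(pops) >= 2)
    scen$intra_env_inter_pop <- inter_population_prediction(
      sel_spec, sel_geno, blups, train_pop = pops[1], train_env = envs[1],
      validation_scope = "same_env", seed = derive_seed(cfg$seed, "sc3"))
  if ("inter_env_inter_pop" %in% cfg$scenarios && length(pops) >= 2 &&
      length(envs) >= 2)
    scen$inter_env_inter_pop <- inter_population_prediction(
      sel_spec, sel_geno, blups, train_pop = pops[1], train_env = envs[1],
      validation_scope = "other_envs", seed = derive_seed(cfg$seed, "sc4"))
  bundle$scenarios <- scen
  say("scenarios: %s", paste(names(scen), collapse = ", "))

  # --- stage: gains --------------------------------------------------------
  r_ab <- scen$intra_env_intra_pop$predictive_ability %||%
    pa_table$pa[1]
  H <- sqrt(max(H2_multi, 1e-6))
  r_ac <- as.numeric(accuracy_from_ability(r_ab, H))
  gr <- vapply(cfg$gains$t_P, function(tp) {
    if (r_ac <= 0) return(NA_real_)   # no useful GS signal at this scale
    efficiency_ratio(r_ac, H, t_G = cfg$gains$t_G, t_P = tp,
                     intensity_ratio = cfg$gains$intensity_ratio)
  }, numeric(1))
  bundle$gains <- data.frame(t_P = cfg$gains$t_P,
                             r_Ab = r_ab, H = H, r_Ac = r_ac, ratio = gr)
  if (anyNA(gr)) say("gains: predictive ability not positive; ratios set NA")
  else say("gains: GS/PS efficiency ratio %s",
           paste(sprintf("%.2f (t_P=%g)", gr, cfg$gains$t_P), collapse = ", "))

  # --- stage: GWAS ---------------------------------------------------------
  gw <- tryCatch(
    score_test_stratified(sel_geno, y_env1, n_pcs = cfg$gwas$n_pcs,
                          threshold = cfg$gwas$threshold),
    error = function(e) { say("GWAS skipped: %s", conditionMessage(e)); NULL })
  bundle$gwas <- gw
  if (!is.null(gw))
    say("GWAS: %d marker(s) at score >= %g", sum(gw$table$significant),
        cfg$gwas$threshold)

  # --- manifest ------------------------------------------------------------
  cfg_plain <- unclass(cfg)
  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("peagain")),
    seed = cfg$seed,
    config_hash = derive_seed(0, paste(utils::capture.output(utils::str(cfg_plain)),
                                       collapse = "")),
    started = format(t0), elapsed_s = as.numeric(Sys.time() - t0, units = "secs"),
    log = log)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  invisible(bundle)
}

# write the main result tables to disk
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$qc, file.path(out_dir, "qc_markers.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$model_grid$pa_table,
                   file.path(out_dir, "model_grid.csv"), row.names = FALSE)
  utils::write.csv(bundle$model_grid$ranking,
                   file.path(out_dir, "rmsd_ranking.csv"), row.names = FALSE)
  utils::write.csv(bundle$gains, file.path(out_dir, "gains.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$gwas))
    utils::write.csv(bundle$gwas$table, file.path(out_dir, "gwas.csv"),
                     row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable study report
#'
#' Renders the [run_study()] bundle as a plain-text report: variance
#' components and heritability, the AMMI summary, the RMSD model ranking,
#' scenario predictive abilities, the gains audit trail (inputs -> ratio) and
#' the association-scan summary. Sections whose stage is absent are flagged
#' as gaps; synthetic data is labelled as such.
#'
#' @param bundle result of [run_study()].
#' @return character vector of report lines (also printed invisibly usable
#'   via `writeLines`).
#' @export
make_report <- function(bundle) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== peagain study report ==")
  add("data: %s", if (!is.null(bundle$sim)) "SYNTHETIC (simulated populations)"
      else "user-supplied")
  if (!is.null(bundle$quantgen)) {
    q <- bundle$quantgen
    add("-- variance components --")
    add("S_G2 = %.4g  S_GE2 = %.4g  S_e2 = %.4g  (ratio G/GE = %.3g)",
        q$vc_multi$S_G2, q$vc_multi$S_GE2, q$vc_multi$S_e2,
        q$vc_multi$S_G2 / max(q$vc_multi$S_GE2, 1e-12))
    add("H2 (across environments) = %.3f", q$H2_multi)
    for (e in names(q$per_env))
      add("  %s: H2 = %.3f, CV_g = %.1f%%", e, q$per_env[[e]]$H2,
          q$per_env[[e]]$cv_g)
  } else add("-- variance components: MISSING --")
  if (!is.null(bundle$ammi)) {
    f <- bundle$ammi$fit
    add("-- AMMI --")
    add("retained axes: %d; %% GEI explained: %s", f$retained_axes,
        paste(sprintf("%.1f", f$pct_gei_explained), collapse = ", "))
    add("top entries: %s", paste(bundle$ammi$top, collapse = ", "))
  } else add("-- AMMI: MISSING --")
  if (!is.null(bundle$model_grid)) {
    add("-- RMSD model ranking --")
    rk <- bundle$model_grid$ranking
    for (i in seq_len(min(5, nrow(rk))))
      add("  %d. %s @ %g  RMSD = %.4f  mean PA = %.3f", i, rk$model[i],
          rk$threshold[i], rk$rmsd[i], rk$mean_pa[i])
  } else add("-- model grid: MISSING --")
  if (length(bundle$scenarios)) {
    add("-- prediction scenarios --")
    for (nm in names(bundle$scenarios)) {
      x <- bundle$scenarios[[nm]]
      if (inherits(x, "cv_result"))
        add("  %s: r_Ab = %.3f", nm, x$predictive_ability)
      else for (e in names(x))
        add("  %s -> %s: r_Ab = %.3f", nm, e, x[[e]]$predictive_ability)
    }
  }
  if (!is.null(bundle$gains)) {
    add("-- GS vs PS gains (audit trail) --")
    for (i in seq_len(nrow(bundle$gains)))
      add("  r_Ab = %.3f, H = %.3f -> r_Ac = %.3f; x1.46 / t_G=0.5 vs H / t_P=%g -> ratio %.3f",
          bundle$gains$r_Ab[i], bundle$gains$H[i], bundle$gains$r_Ac[i],
          bundle$gains$t_P[i], bundle$gains$ratio[i])
  } else add("-- gains: MISSING --")
  if (!is.null(bundle$gwas)) {
    add("-- association scan --")
    add("  %d significant marker(s) at score >= %g; lambda_GC: %s",
        sum(bundle$gwas$table$significant), bundle$gwas$threshold,
        paste(sprintf("%.2f", bundle$gwas$lambda_gc), collapse = ", "))
  } else add("-- association scan: MISSING --")
  ln
}
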