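# shared fixtures, built once per test file and cached

.fixture_cache <- new.env(parent = emptyenv())

# small three-population study: 60 lines, 150 markers
small_study <- function(seed = 101, gei_model = "rank1", h2 = 0.5,
                        gei_sd_ratio = 1.6, lines_per_pop = 20,
                        n_markers = 150, n_qtl = 30) {
  key <- paste(seed, gei_model, h2, gei_sd_ratio, lines_per_pop, n_markers,
               n_qtl, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config(n_markers = n_markers, lines_per_pop = lines_per_pop,
                    n_qtl = n_qtl, h2_per_env = h2,
                    gei_sd_ratio = gei_sd_ratio, gei_model = gei_model,
                    seed = seed)
  sim <- simulate_populations(cfg)
  tm <- make_trait_model(sim$genotypes, cfg)
  ph <- simulate_phenotypes(sim$genotypes, tm, cfg)
  out <- list(cfg = cfg, sim = sim, tm = tm, ph = ph,
              geno = sim$genotypes)
  .fixture_cache[[key]] <- out
  out
}

# per-environment BLUP line values for a study fixture
env_blups <- function(fx, trait = "trait") {
  envs <- sort(unique(fx$ph$environment))
  out <- lapply(envs, function(e) blup_line_means(fx$ph, e, trait))
  names(out) <- envs
  out
}

# mean silhouette width for a clustering (euclidean), hand-rolled
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
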