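#' Configuration for the synthetic RIL-population study generator
#'
#' Bundles all parameters of the synthetic world the package can generate:
#' a small set of fully homozygous parent lines, paired crosses among them
#' giving connected recombinant inbred line (RIL) populations (F1 followed by
#' `inbreeding_generations` selfing meioses, i.e. F6 material by default),
#' several thousand biallelic SNPs laid out on abstract linkage groups, and a
#' polygenic trait measured in a randomized complete block (RCB) design across
#' several environments with controllable heritability and
#' genotype-by-environment interaction (GEI).
#'
#' @param n_parents number of parent lines (default 3).
#' @param n_markers number of biallelic SNP markers.
#' @param lines_per_pop number of RILs per cross.
#' @param crosses list of length-2 integer vectors of parent indices; default
#'   the three paired crosses among three parents.
#' @param inbreeding_generations selfing meioses after the F1 (default 5,
#'   giving F6 lines with expected residual heterozygosity `0.5^5`).
#' @param n_qtl number of additive QTL underlying the trait.
#' @param h2_per_env plot-basis heritability target per environment, each
#'   strictly in (0, 1); recycled to `n_environments`.
#' @param gei_sd_ratio ratio of the GEI effect SD to the genetic effect SD
#'   (>= 0). The default 1.6 corresponds to a genotypic-to-GEI variance ratio
#'   of about 0.39, a grain-yield-like GEI-dominated trait.
#' @param gei_model `"rank1"` (default): GEI as a rank-1 product of a
#'   QTL-driven line score and random environment loadings, so the AMMI PC1
#'   dominates; `"iid"`: independent N(0, V_GE) cell effects, the preset that
#'   makes ANOVA/EMS variance components recover the simulated ratio with
#'   only three environments (see the methods vignette).
#' @param n_environments,n_blocks trial dimensions (defaults 3 and 3).
#' @param block_sd SD of block effects, phenotype units.
#' @param maf_min minimum achievable minor allele frequency (default 0.05).
#' @param missing_rate proportion of genotype calls to mask in `[0, 1)`.
#' @param n_chrom number of linkage groups (default 7, as in pea).
#' @param recomb_per_chrom expected crossovers per chromosome per meiosis.
#' @param env_means per-environment intercepts (default 0).
#' @param seed master seed for all generators.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 3, n_markers = 2000, lines_per_pop = 100,
                       crosses = list(c(1L, 2L), c(2L, 3L), c(1L, 3L)),
                       inbreeding_generations = 5, n_qtl = 100,
                       h2_per_env = 0.5, gei_sd_ratio = 1.6,
                       gei_model = c("rank1", "iid"),
                       n_environments = 3, n_blocks = 3, block_sd = 0.25,
                       maf_min = 0.05, missing_rate = 0,
                       n_chrom = 7, recomb_per_chrom = 1.5,
                       env_means = NULL, seed = 42) {
  cfg <- list(n_parents = as.integer(n_parents),
              n_markers = as.integer(n_markers),
              lines_per_pop = as.integer(lines_per_pop),
              crosses = lapply(crosses, as.integer),
              inbreeding_generations = as.integer(inbreeding_generations),
              n_qtl = as.integer(n_qtl),
              h2_per_env = rep_len(h2_per_env, n_environments),
              gei_sd_ratio = gei_sd_ratio,
              gei_model = match.arg(gei_model, c("rank1", "iid")),
              n_environments = as.integer(n_environments),
              n_blocks = as.integer(n_blocks),
              block_sd = block_sd,
              maf_min = maf_min,
              missing_rate = missing_rate,
              n_chrom = as.integer(n_chrom),
              recomb_per_chrom = recomb_per_chrom,
              env_means = env_means %||% rep(0, n_environments),
              seed = as.integer(seed))
  counts <- c("n_parents", "n_markers", "lines_per_pop",
              "inbreeding_generations", "n_qtl", "n_environments",
              "n_blocks", "n_chrom")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop2(sprintf("`%s` must be >= 1", nm))
  for (cr in cfg$crosses) {
    if (length(cr) != 2L || any(cr < 1L) || any(cr > cfg$n_parents) ||
        cr[1] == cr[2])
      stop2("each cross must be a pair of distinct valid parent indices")
  }
  if (any(cfg$h2_per_env <= 0 | cfg$h2_per_env >= 1))
    stop2("`h2_per_env` values must be strictly in (0, 1)")
  if (cfg$gei_sd_ratio < 0) stop2("`gei_sd_ratio` must be >= 0")
  assert_proportion(cfg$maf_min, "maf_min", 0, 0.5)
  assert_proportion(cfg$missing_rate, "missing_rate", 0, 1, hi_open = TRUE)
  if (length(cfg$env_means) != cfg$n_environments)
    stop2("`env_means` must have one value per environment")
  class(cfg) <- "sim_config"
  cfg
}

#' Abstract linkage map for simulated markers
#'
#' Markers are split into `n_chrom` contiguous, equally sized linkage groups
#' with equally spaced positions in Morgans; chromosome genetic length equals
#' `recomb_per_chrom` (expected crossovers per meiosis).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `marker`, `chrom`, `pos` (Morgans).
#' @export
marker_map <- function(cfg) {
  n <- cfg$n_markers
  chrom <- sort(rep_len(seq_len(cfg$n_chrom), n))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(idx) {
    k <- length(idx)
    if (k == 1) cfg$recomb_per_chrom / 2
    else seq(0, cfg$recomb_per_chrom, length.out = k)
  }), use.names = FALSE)
  data.frame(marker = sprintf("M%05d", seq_len(n)), chrom = chrom, pos = pos)
}

#' Simulate fully homozygous parent lines
#'
#' Each parent is homozygous (dosage 0 or 2) at every marker. Markers where
#' all parents would carry the same allele are redrawn, so that every marker
#' segregates in at least one cross and a population MAF of at least
#' `maf_min` is achievable after crossing.
#'
#' @param cfg a [sim_config()].
#' @return `geno_matrix` of `n_parents` lines (population label "parents").
#' @export
simulate_parents <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(derive_seed(cfg$seed, "parents"), {
    n <- cfg$n_parents; m <- cfg$n_markers
    d <- matrix(2 * stats::rbinom(n * m, 1, 0.5), nrow = n, ncol = m)
    mono <- function(x) apply(x, 2, function(col) length(unique(col)) == 1L)
    bad <- which(mono(d))
    while (length(bad)) {
      d[, bad] <- 2 * stats::rbinom(n * length(bad), 1, 0.5)
      bad <- bad[mono(d[, bad, drop = FALSE])]
    }
    rownames(d) <- sprintf("Par%d", seq_len(n))
    colnames(d) <- sprintf("M%05d", seq_len(m))
    geno_matrix(d, "parents")
  })
}

# one meiosis: recombine two haplotypes along the map, Poisson crossovers
meiosis_gamete <- function(hapA, hapB, chrom_idx, chrom_pos, len) {
  gam <- hapA
  for (c in seq_along(chrom_idx)) {
    idx <- chrom_idx[[c]]
    pos <- chrom_pos[[c]]
    k <- stats::rpois(1, len)
    start <- stats::rbinom(1, 1, 0.5)
    if (k == 0) {
      use_b <- start == 1
      if (use_b) gam[idx] <- hapB[idx]
    } else {
      breaks <- sort(stats::runif(k, 0, len))
      seg <- findInterval(pos, breaks)
      use_b <- (start + seg) %% 2 == 1
      gam[idx][use_b] <- hapB[idx][use_b]
    }
  }
  gam
}

#' Simulate a RIL population from two homozygous parents
#'
#' Builds the F1 and applies `generations` rounds of selfing with crossover
#' sampling (Poisson per chromosome per meiosis) along an abstract linkage
#' map. Every allele traces to one of the parents; after `g` selfing
#' generations the expected per-locus heterozygote frequency at loci where the
#' parents differ is `0.5^g` (residual heterozygosity is retained, matching
#' F6 material).
#'
#' @param parentA,parentB dosage vectors (values 0/2, same marker set).
#' @param n_lines number of RILs to derive.
#' @param generations selfing meioses after the F1 (>= 1).
#' @param recomb_per_chrom expected crossovers per chromosome per meiosis.
#' @param seed integer seed.
#' @param map optional data.frame(marker, chrom, pos); default: 7 equal
#'   linkage groups with uniform positions.
#' @param line_prefix prefix for generated line ids.
#' @return `geno_matrix` of the RILs (single population).
#' @export
simulate_ril_population <- function(parentA, parentB, n_lines, generations,
                                    recomb_per_chrom = 1.5, seed = 1,
                                    map = NULL, line_prefix = "RIL") {
  if (length(parentA) != length(parentB))
    stop2("parents must share the same marker set")
  if (generations < 1) stop2("`generations` must be >= 1")
  m <- length(parentA)
  if (is.null(map)) {
    cfg <- sim_config(n_markers = m, recomb_per_chrom = recomb_per_chrom,
                      seed = seed)
    map <- marker_map(cfg)
  }
  if (nrow(map) != m) stop2("map does not match the marker set")
  chrom_idx <- split(seq_len(m), map$chrom)
  chrom_pos <- split(map$pos, map$chrom)
  pa <- as.numeric(parentA) / 2   # allele indicators 0/1
  pb <- as.numeric(parentB) / 2
  with_local_seed(seed, {
    d <- matrix(0, nrow = n_lines, ncol = m)
    for (l in seq_len(n_lines)) {
      hapA <- pa; hapB <- pb                      # F1
      for (g in seq_len(generations)) {
        g1 <- meiosis_gamete(hapA, hapB, chrom_idx, chrom_pos, recomb_per_chrom)
        g2 <- meiosis_gamete(hapA, hapB, chrom_idx, chrom_pos, recomb_per_chrom)
        hapA <- g1; hapB <- g2
      }
      d[l, ] <- hapA + hapB
    }
    rownames(d) <- sprintf("%s_%03d", line_prefix, seq_len(n_lines))
    colnames(d) <- names(parentA) %||% sprintf("M%05d", seq_len(m))
    geno_matrix(d, line_prefix)
  })
}

#' Simulate the full set of connected RIL populations
#'
#' Convenience wrapper: simulates the parents, then one RIL population per
#' cross in `cfg$crosses`, stacking everything into a single genotype matrix
#' with per-cross population labels (e.g. `"Par1xPar2"`).
#'
#' @param cfg a [sim_config()].
#' @param include_parents keep the parent lines in the returned matrix
#'   (population label "parents")? Default `FALSE`.
#' @return list with elements `genotypes` (`geno_matrix` of all RILs),
#'   `parents` (`geno_matrix`), `map` (marker map).
#' @export
simulate_populations <- function(cfg, include_parents = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  parents <- simulate_parents(cfg)
  map <- marker_map(cfg)
  mats <- list(); pops <- character(0)
  for (i in seq_along(cfg$crosses)) {
    cr <- cfg$crosses[[i]]
    nm <- sprintf("Par%dxPar%d", cr[1], cr[2])
    ril <- simulate_ril_population(parents$dosage[cr[1], ],
                                   parents$dosage[cr[2], ],
                                   n_lines = cfg$lines_per_pop,
                                   generations = cfg$inbreeding_generations,
                                   recomb_per_chrom = cfg$recomb_per_chrom,
                                   seed = derive_seed(cfg$seed, nm),
                                   map = map, line_prefix = nm)
    mats[[i]] <- ril$dosage
    pops <- c(pops, ril$populations)
  }
  d <- do.call(rbind, mats)
  if (include_parents) {
    d <- rbind(d, parents$dosage)
    pops <- c(pops, parents$populations)
  }
  list(genotypes = geno_matrix(d, pops), parents = parents, map = map)
}

#' Build an additive polygenic trait model
#'
#' Samples `n_qtl` QTL among the markers with standard-normal additive
#' effects, rescaled so the SD of genetic values over the supplied lines is 1
#' phenotype unit. GEI is injected as a low-rank (rank-1 by default) structure:
#' a zero-mean environment loading vector times per-QTL interaction slopes,
#' double-centered so it contributes pure interaction variance, and rescaled so
#' that the SD of GEI effects over (line, environment) cells equals
#' `gei_sd_ratio` times the genetic SD. With `gei_sd_ratio = 0`, per-line
#' genetic values are identical across environments.
#'
#' @param genotypes `geno_matrix` of the lines the trait will be simulated on.
#' @param cfg a [sim_config()].
#' @param seed optional seed (default derived from `cfg$seed`).
#' @return list of class `trait_model`: `qtl_indices`, `main_effects`,
#'   `env_effects` (QTL x environment deviation matrix), `env_means`,
#'   plus cached per-line `genetic_values` and `gei_values`.
#' @export
make_trait_model <- function(genotypes, cfg, seed = NULL) {
  g <- as_geno(genotypes)
  m <- ncol(g$dosage)
  if (cfg$n_qtl > m) stop2("more QTL than markers")
  with_local_seed(seed %||% derive_seed(cfg$seed, "trait"), {
    qtl <- sort(sample.int(m, cfg$n_qtl))
    Q <- g$dosage[, qtl, drop = FALSE]
    if (anyNA(Q)) stop2("genotypes must be complete to define a trait model")
    a <- stats::rnorm(cfg$n_qtl)
    gv <- drop(Q %*% a)
    s <- stats::sd(gv)
    if (s > 0) { a <- a / s; gv <- gv / s }
    gv <- gv - mean(gv)
    e <- cfg$n_environments
    # GEI as an uncentered rank-1 product w_i * delta_j with independent
    # random environment loadings: this reproduces, in expectation, the EMS
    # structure of iid interaction effects (so the ANOVA components recover
    # the simulated variances) while keeping the interaction matrix rank 1
    # (so AMMI PC1 dominates).
    target <- cfg$gei_sd_ratio          # genetic SD is 1 by construction
    if (target > 0 && (cfg$gei_model %||% "rank1") == "iid") {
      gei <- matrix(stats::rnorm(length(gv) * e, 0, target), ncol = e)
      env_eff <- matrix(0, cfg$n_qtl, e)
    } else {
      b <- stats::rnorm(cfg$n_qtl)
      w <- drop(Q %*% b)
      sd_w <- stats::sd(w)
      if (sd_w > 0 && target > 0) {
        w <- (w - mean(w)) / sd_w
        b <- b / sd_w
        delta <- stats::rnorm(e, 0, target)
        gei <- w %o% delta
        env_eff <- b %o% delta
      } else {
        gei <- matrix(0, length(gv), e)
        env_eff <- matrix(0, cfg$n_qtl, e)
      }
    }
    structure(list(qtl_indices = qtl, main_effects = a,
                   env_effects = env_eff, env_means = cfg$env_means,
                   genetic_values = stats::setNames(gv, line_ids(g)),
                   gei_values = {
                     rownames(gei) <- line_ids(g)
                     colnames(gei) <- sprintf("E%d", seq_len(e))
                     gei
                   }),
              class = "trait_model")
  })
}

#' Simulate multi-environment RCB phenotypes
#'
#' Every line is observed in every block of every environment (full
#' randomized complete block design). Plot values are
#' `env mean + genetic value + GEI deviation + block effect + residual`,
#' with the residual SD per environment chosen so that the plot-basis
#' heritability `S_G^2 / (S_G^2 + S_e^2)` within that environment hits the
#' `cfg$h2_per_env` target.
#'
#' @param genotypes `geno_matrix` (used for line ids and population labels).
#' @param trait a `trait_model` from [make_trait_model()], or a named list of
#'   them for several traits.
#' @param cfg a [sim_config()].
#' @param seed optional seed (default derived from `cfg$seed`).
#' @return data.frame with columns `line`, `population`, `environment`,
#'   `block` and one numeric column per trait.
#' @export
simulate_phenotypes <- function(genotypes, trait, cfg, seed = NULL) {
  g <- as_geno(genotypes)
  traits <- if (inherits(trait, "trait_model")) list(trait = trait) else trait
  stopifnot(length(traits) >= 1, all(vapply(traits, inherits, TRUE, "trait_model")))
  lines <- line_ids(g)
  e <- cfg$n_environments; r <- cfg$n_blocks
  envs <- sprintf("E%d", seq_len(e))
  blocks <- sprintf("B%d", seq_len(r))
  design <- expand.grid(line = lines, environment = envs, block = blocks,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(design$environment, design$block, design$line), ]
  rownames(design) <- NULL
  out <- data.frame(line = design$line,
                    population = unname(g$populations[design$line]),
                    environment = design$environment,
                    block = design$block,
                    stringsAsFactors = FALSE)
  with_local_seed(seed %||% derive_seed(cfg$seed, "phenotypes"), {
    for (nm in names(traits)) {
      tm <- traits[[nm]]
      if (!all(lines %in% names(tm$genetic_values)))
        stop2("trait model does not cover all lines")
      gv <- tm$genetic_values[lines]
      gei <- tm$gei_values[lines, , drop = FALSE]
      blk <- matrix(stats::rnorm(e * r, 0, cfg$block_sd), nrow = e)
      y <- numeric(nrow(out))
      for (j in seq_len(e)) {
        u <- gv + gei[, j]
        v <- stats::var(u)
        h2 <- cfg$h2_per_env[j]
        sd_e <- if (v > 0) sqrt(v * (1 - h2) / h2) else 1
        for (b in seq_len(r)) {
          sel <- out$environment == envs[j] & out$block == blocks[b]
          y[sel] <- cfg$env_means[j] + u[out$line[sel]] + blk[j, b] +
            stats::rnorm(sum(sel), 0, sd_e)
        }
      }
      out[[nm]] <- y
    }
  })
  out
}

#' Mask genotype calls as missing
#'
#' Sets entries to `NA` independently with probability `missing_rate`,
#' emulating GBS missingness. Non-missing entries are unchanged.
#'
#' @param genotypes `geno_matrix`.
#' @param missing_rate proportion in `[0, 1)`.
#' @param seed integer seed.
#' @return `geno_matrix` with masked entries.
#' @export
mask_missing <- function(genotypes, missing_rate, seed = 1) {
  g <- as_geno(genotypes)
  assert_proportion(missing_rate, "missing_rate", 0, 1, hi_open = TRUE)
  if (missing_rate == 0) return(g)
  with_local_seed(seed, {
    d <- g$dosage
    mask <- stats::runif(length(d)) < missing_rate
    d[mask] <- NA
    geno_matrix(d, g$populations)
  })
}
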