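#' Filter markers by missing-call rate
#'
#' Removes markers whose fraction of missing calls over lines exceeds
#' `threshold` (strictly greater). Lines are untouched. This is the first QC
#' step; the minor-allele-frequency filter ([filter_maf()]) follows it, and
#' imputation comes last.
#'
#' @param g `geno_matrix`.
#' @param threshold maximum allowed missing fraction in `[0, 1]`.
#' @return filtered `geno_matrix`.
#' @export
filter_missing_rate <- function(g, threshold) {
  g <- as_geno(g)
  assert_proportion(threshold, "threshold", 0, 1)
  miss <- colMeans(is.na(g$dosage))
  keep <- miss <= threshold
  geno_matrix(g$dosage[, keep, drop = FALSE], g$populations)
}

#' Minor allele frequency of each marker
#'
#' MAF is computed on non-missing dosages as `min(p, 1 - p)` with
#' `p = mean(dosage) / 2`.
#'
#' @param g `geno_matrix`.
#' @return named numeric vector per marker (NaN for all-missing markers).
#' @export
maf <- function(g) {
  g <- as_geno(g)
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  stats::setNames(pmin(p, 1 - p), marker_ids(g))
}

#' Filter monomorphic and low-MAF markers
#'
#' Removes markers that are monomorphic (among observed calls) or whose minor
#' allele frequency is strictly below `min_maf`; a marker with MAF exactly
#' equal to `min_maf` is retained.
#'
#' @param g `geno_matrix`.
#' @param min_maf minimum MAF in `[0, 0.5]` (default 0.05).
#' @return filtered `geno_matrix`.
#' @export
filter_maf <- function(g, min_maf = 0.05) {
  g <- as_geno(g)
  assert_proportion(min_maf, "min_maf", 0, 0.5)
  f <- maf(g)
  poly <- apply(g$dosage, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && length(unique(x)) > 1L
  })
  keep <- poly & !is.na(f) & f >= min_maf & f > 0
  geno_matrix(g$dosage[, keep, drop = FALSE], g$populations)
}

#' Impute missing genotype calls
#'
#' Three methods are available:
#' * `"mode"` (default): per-marker most frequent observed dosage
#'   (ties broken toward the smaller dosage);
#' * `"marker_mean_rounded"`: per-marker mean dosage rounded to the nearest
#'   of 0/1/2;
#' * `"iterative_forest"`: iterative random-forest imputation in the spirit of
#'   MissForest — genotypes treated as categorical, each incomplete marker
#'   predicted from its most correlated companion markers by a classification
#'   random forest (100 trees), iterating up to `max_iter` passes until the
#'   imputed values stop changing. This is the heavyweight, most accurate
#'   option; mode imputation is the fast default.
#'
#' @param g `geno_matrix`.
#' @param method one of `"mode"`, `"marker_mean_rounded"`,
#'   `"iterative_forest"`.
#' @param seed integer seed (used by the forest method).
#' @param n_tree,max_iter,n_predictors forest parameters: trees per marker
#'   (default 100), maximum sweeps (default 10), companion markers used as
#'   predictors (default 30).
#' @return complete `geno_matrix`; non-missing entries are unchanged.
#' @export
impute_missing <- function(g, method = c("mode", "marker_mean_rounded",
                                         "iterative_forest"),
                           seed = 1, n_tree = 100, max_iter = 10,
                           n_predictors = 30) {
  g <- as_geno(g)
  method <- match.arg(method)
  d <- g$dosage
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing))
    stop2("cannot impute all-missing marker(s): ",
          paste(marker_ids(g)[all_missing], collapse = ", "))
  if (!anyNA(d)) return(g)
  if (method == "mode") {
    for (j in which(colSums(is.na(d)) > 0)) {
      x <- d[, j]
      tab <- table(factor(x[!is.na(x)], levels = c(0, 1, 2)))
      d[is.na(x), j] <- as.numeric(names(tab)[which.max(tab)])
    }
  } else if (method == "marker_mean_rounded") {
    for (j in which(colSums(is.na(d)) > 0)) {
      x <- d[, j]
      v <- round(mean(x, na.rm = TRUE))
      d[is.na(x), j] <- min(2, max(0, v))
    }
  } else {
    d <- impute_forest_matrix(d, seed = seed, n_tree = n_tree,
                              max_iter = max_iter,
                              n_predictors = n_predictors)
  }
  geno_matrix(d, g$populations)
}

# MissForest-style sweep built on the compiled random-forest classifier.
impute_forest_matrix <- function(d, seed, n_tree, max_iter, n_predictors) {
  miss_cols <- which(colSums(is.na(d)) > 0)
  # initialize with mode
  init <- d
  for (j in miss_cols) {
    x <- d[, j]
    tab <- table(factor(x[!is.na(x)], levels = c(0, 1, 2)))
    init[is.na(x), j] <- as.numeric(names(tab)[which.max(tab)])
  }
  cur <- init
  # predictor sets: most correlated complete-initialized markers
  p <- ncol(d)
  with_local_seed(seed, {
    cc <- suppressWarnings(stats::cor(init))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    pred_sets <- lapply(miss_cols, function(j) {
      ord <- order(abs(cc[, j]), decreasing = TRUE)
      setdiff(ord, j)[seq_len(min(n_predictors, p - 1))]
    })
    names(pred_sets) <- as.character(miss_cols)
    prev_change <- Inf
    for (iter in seq_len(max_iter)) {
      changed <- 0L
      for (k in seq_along(miss_cols)) {
        j <- miss_cols[k]
        na_rows <- which(is.na(d[, j]))
        obs_rows <- which(!is.na(d[, j]))
        X <- cur[, pred_sets[[k]], drop = FALSE]
        pred <- rf_classify(X[obs_rows, , drop = FALSE],
                            as.integer(d[obs_rows, j]),
                            X[na_rows, , drop = FALSE],
                            as.integer(n_tree),
                            as.integer(sample.int(.Machine$integer.max, 1)))
        changed <- changed + sum(pred != cur[na_rows, j])
        cur[na_rows, j] <- pred
      }
      if (changed == 0L || changed >= prev_change) break
      prev_change <- changed
    }
  })
  cur
}

#' Genomic (VanRaden) kinship matrix
#'
#' `K = Z Z' / c` with `Z` the column-centered dosage matrix and
#' `c = 2 * sum(p_j (1 - p_j))` over markers, where `p_j` is the alternate
#' allele frequency. The result is symmetric positive semidefinite up to
#' numerical tolerance and is the genomic covariance used by G-BLUP.
#'
#' @param g complete `geno_matrix` (no missing calls).
#' @return matrix of class `kinship_matrix`, lines x lines.
#' @export
compute_kinship <- function(g) {
  g <- as_geno(g)
  d <- g$dosage
  if (anyNA(d)) stop2("kinship requires complete genotypes; impute first")
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  c0 <- 2 * sum(p * (1 - p))
  if (c0 <= 0) stop2("all markers monomorphic; kinship undefined")
  K <- tcrossprod(Z) / c0
  K <- (K + t(K)) / 2
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Nei's standard genetic distance
#'
#' `D = -ln( J_AB / sqrt(J_A J_B) )` where, for biallelic loci with alternate
#' allele frequencies `p_A`, `p_B`, the identity terms
#' `J_A = mean(p_A^2 + (1-p_A)^2)`, `J_B` likewise, and
#' `J_AB = mean(p_A p_B + (1-p_A)(1-p_B))`, averaged over loci before taking
#' the ratio. Identical frequency profiles give `D = 0`; `J_AB = 0` yields
#' `Inf` rather than an error.
#'
#' @param freqA,freqB alternate-allele frequency vectors in `[0, 1]`, same
#'   marker set.
#' @return nonnegative distance (possibly `Inf`).
#' @export
nei_distance <- function(freqA, freqB) {
  if (length(freqA) != length(freqB))
    stop2("frequency vectors must cover the same markers")
  if (any(freqA < 0 | freqA > 1 | freqB < 0 | freqB > 1, na.rm = TRUE))
    stop2("frequencies must be in [0, 1]")
  jA <- mean(freqA^2 + (1 - freqA)^2)
  jB <- mean(freqB^2 + (1 - freqB)^2)
  jAB <- mean(freqA * freqB + (1 - freqA) * (1 - freqB))
  if (jAB <= 0) return(Inf)
  max(0, -log(jAB / sqrt(jA * jB)))
}

#' Per-population alternate allele frequencies
#'
#' @param g `geno_matrix`.
#' @return matrix populations x markers of alternate allele frequencies.
#' @export
allele_frequencies <- function(g) {
  g <- as_geno(g)
  pops <- unique(g$populations)
  t(vapply(pops, function(pp) {
    colMeans(g$dosage[g$populations == pp, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(g$dosage))))
}
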