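make_miss_matrix <- function() {
  # 100 lines x 5 markers with missing counts 0, 5, 12, 25, 40
  set.seed(1)
  d <- matrix(rbinom(500, 2, 0.4), nrow = 100,
              dimnames = list(sprintf("L%03d", 1:100), paste0("M", 1:5)))
  for (j in 2:5) d[seq_len(c(0, 5, 12, 25, 40)[j]), j] <- NA
  geno_matrix(d)
}

test_that("missing-rate filter keeps exactly the markers at or below threshold", {
  g <- make_miss_matrix()
  expect_equal(ncol(filter_missing_rate(g, 0.10)$dosage), 2L)
  expect_equal(ncol(filter_missing_rate(g, 1.0)$dosage), 5L)
  expect_equal(ncol(filter_missing_rate(g, 0)$dosage), 1L)
  # idempotence
  f1 <- filter_missing_rate(g, 0.10)
  expect_identical(filter_missing_rate(f1, 0.10)$dosage, f1$dosage)
})

test_that("MAF filter removes monomorphic and rare markers with a strict <", {
  d <- matrix(0, nrow = 100, ncol = 3,
              dimnames = list(sprintf("L%03d", 1:100), c("mono", "rare", "edge")))
  d[1:4, "rare"] <- 2          # p = 0.04 < 0.05 -> removed
  d[1:5, "edge"] <- 2          # p = 0.05 -> retained
  g <- geno_matrix(d)
  kept <- filter_maf(g, 0.05)
  expect_identical(colnames(kept$dosage), "edge")
  # idempotence and order-independence on complete data
  fx <- small_study()
  a <- filter_maf(filter_missing_rate(fx$geno, 0.1), 0.05)
  b <- filter_missing_rate(filter_maf(fx$geno, 0.05), 0.1)
  expect_identical(colnames(a$dosage), colnames(b$dosage))
  expect_identical(filter_maf(a, 0.05)$dosage, a$dosage)
})

test_that("imputation fills all gaps without touching observed calls", {
  d <- rbind(c(0, 0), c(0, 2), c(0, 1), c(2, NA), c(NA, 2))
  rownames(d) <- paste0("L", 1:5); colnames(d) <- c("A", "B")
  g <- geno_matrix(d)
  out <- impute_missing(g, "mode")
  expect_false(anyNA(out$dosage))
  expect_equal(out$dosage["L5", "A"], 0)    # mode of {0,0,0,2}
  obs <- !is.na(d)
  expect_identical(out$dosage[obs], d[obs])
  # identity on complete input
  fx <- small_study()
  expect_identical(impute_missing(fx$geno, "mode"), fx$geno)
  # all-missing marker refused with its name
  d2 <- d; d2[, "B"] <- NA
  expect_error(impute_missing(geno_matrix(d2)), "B")
})

test_that("iterative forest imputation is at least as accurate as mode", {
  fx <- small_study(seed = 77, n_markers = 80, lines_per_pop = 20)
  g <- fx$geno
  masked <- mask_missing(g, 0.10, seed = 5)
  hidden <- is.na(masked$dosage)
  mode_fit <- impute_missing(masked, "mode")
  rf_fit <- impute_missing(masked, "iterative_forest", seed = 11,
                           n_tree = 50, n_predictors = 20)
  err_mode <- mean(mode_fit$dosage[hidden] != g$dosage[hidden])
  err_rf <- mean(rf_fit$dosage[hidden] != g$dosage[hidden])
  expect_lte(err_rf, err_mode)
  expect_false(anyNA(rf_fit$dosage))
  obs <- !hidden
  expect_identical(rf_fit$dosage[obs], g$dosage[obs])
})

test_that("kinship matches the VanRaden closed form and its invariances", {
  # 2 lines, 1 marker, dosages (0, 2): Z = (-1, 1), c = 0.5
  g <- geno_matrix(matrix(c(0, 2), ncol = 1,
                          dimnames = list(c("a", "b"), "M1")))
  K <- compute_kinship(g)
  expect_equal(unclass(K), matrix(c(2, -2, -2, 2), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  fx <- small_study()
  d <- fx$geno$dosage
  d <- rbind(d, dup = d[1, ])
  K2 <- compute_kinship(geno_matrix(d))
  expect_lt(max(abs(K2 - t(K2))), 1e-10)
  expect_equal(unname(K2[1, ]), unname(K2["dup", ]))
  expect_error(compute_kinship(mask_missing(fx$geno, 0.1)), "complete")
})

test_that("kinship ties parents to their offspring more than to other parents", {
  cfg <- sim_config(n_markers = 300, lines_per_pop = 15, n_qtl = 10, seed = 21)
  sim <- simulate_populations(cfg, include_parents = TRUE)
  K <- compute_kinship(sim$genotypes)
  off <- grep("^Par1xPar2", rownames(K), value = TRUE)
  k_par_off <- mean(K["Par1", off])
  k_par_par <- K["Par1", "Par3"]
  expect_gt(k_par_off, k_par_par)
})

test_that("Nei distance follows the closed form", {
  expect_equal(nei_distance(c(0.2, 0.7), c(0.2, 0.7)), 0)
  d <- nei_distance(0.9, 0.6)
  expect_equal(d, -log(0.58 / sqrt(0.82 * 0.52)), tolerance = 1e-12)
  expect_equal(round(d, 4), 0.1185)
  expect_equal(nei_distance(c(0.3, 0.8), c(0.5, 0.1)),
               nei_distance(c(0.5, 0.1), c(0.3, 0.8)))
  expect_identical(nei_distance(1, 0), Inf)
  expect_error(nei_distance(0.5, 1.2), "\\[0, 1\\]")
})

test_that("genotype IO round-trips through CSV and VCF", {
  fx <- small_study(seed = 31, n_markers = 40, lines_per_pop = 5)
  g <- mask_missing(fx$geno, 0.05, seed = 2)
  csv <- tempfile(fileext = ".csv")
  write_genotypes(g, csv)
  back <- read_genotypes(csv, populations = g$populations)
  expect_equal(back$dosage, g$dosage)
  expect_identical(back$populations, g$populations)
  vcf <- tempfile(fileext = ".vcf")
  write_genotypes(g, vcf)
  back2 <- read_genotypes(vcf, populations = g$populations)
  expect_equal(unname(back2$dosage), unname(g$dosage))
  expect_identical(colnames(back2$dosage), colnames(g$dosage))
})

test_that("multi-allelic VCF records are rejected with the marker named", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\tgoodM\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t200\tbadM\tA\tT,C\t.\tPASS\t.\tGT\t0/0\t1/2"), vcf)
  expect_error(read_genotypes(vcf), "badM")
  ok <- read_genotypes(vcf, multiallelic = "drop")
  expect_equal(ncol(ok$dosage), 1L)
})
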