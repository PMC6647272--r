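# genotype and phenotype file IO

#' Read a genotype matrix from VCF or CSV
#'
#' VCF input (GT field, biallelic SNPs) is parsed with VariantAnnotation and
#' mapped to alternate-allele dosage: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`,
#' missing GT -> `NA`. Multi-allelic records are rejected (naming the marker)
#' or dropped, per `multiallelic`. CSV dialect: first column the line id,
#' header row the marker ids, missing encoded `NA`.
#'
#' @param path file path.
#' @param format `"vcf"` or `"csv"` (default guessed from the extension).
#' @param populations optional named vector line -> population label, or a
#'   two-column CSV path (`line,population`).
#' @param multiallelic `"error"` (strict, default) or `"drop"`.
#' @return `geno_matrix`.
#' @export
read_genotypes <- function(path, format = NULL, populations = NULL,
                           multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop2("file not found: ", path)
  format <- format %||% if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv"
  if (is.character(populations) && length(populations) == 1L &&
      file.exists(populations)) {
    pm <- utils::read.csv(populations, stringsAsFactors = FALSE)
    populations <- stats::setNames(pm[[2]], pm[[1]])
  }
  if (format == "vcf") {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop2("reading VCF requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    alt <- VariantAnnotation::alt(vcf)
    n_alt <- S4Vectors::elementNROWS(alt)
    multi <- which(n_alt > 1)
    if (length(multi)) {
      if (multiallelic == "error")
        stop2("multi-allelic record(s): ",
              paste(rownames(vcf)[multi], collapse = ", "))
      vcf <- vcf[n_alt <= 1, ]
    }
    gt <- VariantAnnotation::geno(vcf)$GT   # markers x samples
    code <- function(x) {
      x <- gsub("\\|", "/", x)
      ifelse(x %in% c("0/0"), 0,
             ifelse(x %in% c("0/1", "1/0"), 1,
                    ifelse(x %in% c("1/1"), 2, NA_real_)))
    }
    d <- t(matrix(code(as.vector(gt)), nrow = nrow(gt),
                  dimnames = dimnames(gt)))
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    d <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(d) <- "double"
    rownames(d) <- tab[[1]]
  }
  geno_matrix(d, populations %||% "pop1")
}

#' Write a genotype matrix to VCF or CSV
#'
#' The VCF writer emits a minimal VCF v4.2 with unphased GT calls on synthetic
#' coordinates (one record per marker; `map` supplies chromosome/position when
#' available). Round-trips through [read_genotypes()].
#'
#' @param g `geno_matrix`.
#' @param path output path.
#' @param format `"vcf"` or `"csv"` (default from extension).
#' @param map optional data.frame(marker, chrom, pos) for VCF coordinates.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = NULL, map = NULL) {
  g <- as_geno(g)
  format <- format %||% if (grepl("\\.vcf$", path)) "vcf" else "csv"
  d <- g$dosage
  if (format == "csv") {
    out <- data.frame(line = rownames(d), d, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
    return(invisible(path))
  }
  m <- ncol(d)
  if (is.null(map)) {
    map <- data.frame(marker = colnames(d), chrom = 1L, pos = seq_len(m))
  } else {
    map <- map[match(colnames(d), map$marker), ]
  }
  gt <- matrix("./.", nrow = m, ncol = nrow(d))
  gt[t(d) == 0] <- "0/0"; gt[t(d) == 1] <- "0/1"; gt[t(d) == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=peagain",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- vapply(seq_len(m), function(i) {
    paste(c(map$chrom[i], round(as.numeric(map$pos[i]) * 1e6) + i, map$marker[i],
            "A", "T", ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a long-format phenotype table
#'
#' CSV with header `line,population,environment,block,<trait...>`.
#'
#' @param ph phenotype data.frame as produced by [simulate_phenotypes()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_phenotypes <- function(ph, path) {
  utils::write.csv(ph, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
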