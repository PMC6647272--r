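#' Genotype matrix container
#'
#' A lightweight container for a lines x markers SNP dosage matrix coded as
#' the count of the alternate allele (0, 1, 2, or `NA` for a missing call),
#' together with the mapping of each line to its population of origin
#' (e.g. the RIL population it belongs to). All quality-control, genomic
#' prediction and association functions in the package consume this class.
#'
#' @param dosage integer or numeric matrix, lines in rows and markers in
#'   columns; values restricted to 0, 1, 2 or `NA`. Row and column names are
#'   used as line and marker identifiers (generated when absent).
#' @param populations character or factor giving the population label of each
#'   line, either unnamed in row order or named by line id. A single value is
#'   recycled.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   (the matrix) and `populations` (named character vector by line).
#' @examples
#' g <- geno_matrix(rbind(L1 = c(0, 2, 1), L2 = c(2, 0, NA)), "popA")
#' dim(g)
#' @export
geno_matrix <- function(dosage, populations = "pop1") {
  if (!is.matrix(dosage)) stop2("`dosage` must be a matrix")
  storage.mode(dosage) <- "double"
  bad <- !(dosage %in% c(0, 1, 2)) & !is.na(dosage)
  if (any(bad)) stop2("dosage values must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("L%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("M%05d", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage))) stop2("duplicated line ids")
  if (anyDuplicated(colnames(dosage))) stop2("duplicated marker ids")
  populations <- as.character(populations)
  if (length(populations) == 1L)
    populations <- rep(populations, nrow(dosage))
  if (!is.null(names(populations))) {
    if (!all(rownames(dosage) %in% names(populations)))
      stop2("`populations` names do not cover all lines")
    populations <- populations[rownames(dosage)]
  } else {
    if (length(populations) != nrow(dosage))
      stop2("`populations` must have one label per line")
    names(populations) <- rownames(dosage)
  }
  structure(list(dosage = dosage, populations = populations),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosage
  miss <- mean(is.na(d))
  cat(sprintf("<geno_matrix> %d lines x %d markers, %d population(s), %.1f%% missing\n",
              nrow(d), ncol(d), length(unique(x$populations)), 100 * miss))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  d <- x$dosage[i, j, drop = FALSE]
  geno_matrix(d, x$populations[rownames(d)])
}

line_ids <- function(g) rownames(g$dosage)
marker_ids <- function(g) colnames(g$dosage)

as_geno <- function(g) {
  if (inherits(g, "geno_matrix")) return(g)
  if (is.matrix(g)) return(geno_matrix(g))
  stop2("expected a geno_matrix")
}
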