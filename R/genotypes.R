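#' SNP genotype matrix with marker map
#'
#' Lightweight container for a lines x markers diploid dosage matrix (values
#' 0/1/2, `NA` for missing) plus the genetic map of the (possibly partial)
#' subset of mapped markers.
#'
#' @param dosage numeric matrix, lines x markers, with unique dimnames.
#' @param map data.frame with columns `marker`, `chrom`, `pos_cM`; markers
#'   absent from `map` are treated as unmapped.
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(dosage, map = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage matrix must have line and marker dimnames")
  if (anyDuplicated(rownames(dosage))) stop("line_ids must be unique")
  if (anyDuplicated(colnames(dosage))) stop("marker_ids must be unique")
  storage.mode(dosage) <- "double"
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(map)) {
    stopifnot(all(c("marker", "chrom", "pos_cM") %in% names(map)))
    map <- map[map$marker %in% colnames(dosage), , drop = FALSE]
  }
  structure(list(dosage = dosage, map = map), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("<genotypes> %d lines x %d markers (%.2f%% missing, %d mapped)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage)),
              if (is.null(x$map)) 0L else nrow(x$map)))
  invisible(x)
}

#' Per-marker allele frequency and minor allele frequency
#'
#' Frequencies are computed from allele counts over non-missing dosages; a
#' heterozygote contributes one copy of each allele.
#'
#' @param G a `genotypes` object.
#' @return `allele_freq`: named vector of counted-allele frequencies;
#'   `maf`: named vector of minor allele frequencies.
#' @export
allele_freq <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
maf <- function(G) {
  p <- allele_freq(G)
  pmin(p, 1 - p)
}

#' Per-marker missing fraction
#' @param G a `genotypes` object.
#' @export
missing_fraction <- function(G) {
  colMeans(is.na(G$dosage))
}
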