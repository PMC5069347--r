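#' Filter SNPs on missingness and minor allele frequency
#'
#' Markers are screened in a fixed order with first-failing-filter
#' attribution: a marker whose missing fraction exceeds `max_missing` is
#' charged to the missingness filter; among the remaining markers, those with
#' MAF below `maf_min` (computed on non-missing dosages, a heterozygote
#' contributing one copy of each allele) are charged to the MAF filter.
#' Defaults follow the usual chip-QC practice of discarding MAF < 0.01 or
#' > 10 % missing values.
#'
#' @param G a [genotypes()] object.
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @return List with `genotypes` (filtered) and `report`, a `qc_report`:
#'   `n_input`, `n_passed`, `removed` (named counts per filter, first-failing
#'   attribution so `n_input = n_passed + sum(removed)`), and the per-marker
#'   `maf` and `missing_fraction` of the input.
#' @export
filter_snps <- function(G, maf_min = 0.01, max_missing = 0.10) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  mf <- missing_fraction(G)
  mafs <- maf(G)
  fail_miss <- mf > max_missing | is.nan(mafs)     # fully missing counts here
  fail_maf <- !fail_miss & mafs < maf_min
  keep <- !fail_miss & !fail_maf
  if (!any(keep))
    stop("all markers removed by QC filters (maf_min = ", maf_min,
         ", max_missing = ", max_missing, ")")
  report <- structure(list(
    n_input = ncol(G$dosage),
    n_passed = sum(keep),
    removed = c(missingness = sum(fail_miss), maf = sum(fail_maf)),
    maf = mafs,
    missing_fraction = mf,
    thresholds = c(maf_min = maf_min, max_missing = max_missing)),
    class = "qc_report")
  list(genotypes = genotypes(G$dosage[, keep, drop = FALSE], G$map),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d markers in, %d passed (removed: %d missingness, %d MAF)\n",
              x$n_input, x$n_passed, x$removed[["missingness"]],
              x$removed[["maf"]]))
  invisible(x)
}

#' Impute missing genotypes from marginal genotype-class distributions
#'
#' Each missing entry is replaced by a draw from its marker's empirical
#' distribution over the observed genotype classes (0/1/2). Observed entries
#' are untouched; the output has no missing values. Expected allele
#' frequencies are preserved by construction.
#'
#' @param G a [genotypes()] object; every marker must have at least one
#'   observed value (run [filter_snps()] first).
#' @param seed integer seed.
#' @return A [genotypes()] object without missing values.
#' @export
impute_marginal <- function(G, seed = 1L) {
  d <- G$dosage
  n_miss <- colSums(is.na(d))
  if (any(n_miss == nrow(d)))
    stop("fully-missing marker(s): ",
         paste(utils::head(colnames(d)[n_miss == nrow(d)], 5), collapse = ", "),
         " — filter before imputing")
  if (all(n_miss == 0L)) return(G)
  with_stream(seed, "impute", {
    for (j in which(n_miss > 0L)) {
      obs <- d[!is.na(d[, j]), j]
      miss <- is.na(d[, j])
      d[miss, j] <- sample(obs, sum(miss), replace = TRUE)
    }
    genotypes(d, G$map)
  })
}
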