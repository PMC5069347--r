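#' Pairwise linkage disequilibrium (r2) for mapped intra-chromosomal markers
#'
#' Computes `r2` as the squared Pearson correlation of dosage vectors — the
#' composite LD estimator for unphased genotypes. For fully homozygous
#' material it equals the haplotype-frequency r2 of Hill and Robertson,
#' `D^2 / (p_A p_a p_B p_b)`, and it requires no phasing for partially
#' heterozygous S2 lines. Only pairs of mapped markers on the same chromosome
#' within `max_distance_cM` are reported; pairs involving a monomorphic marker
#' are skipped and counted.
#'
#' @param G a [genotypes()] object with no missing values (impute first) and a
#'   marker map.
#' @param max_distance_cM maximum map distance between pair members.
#' @return data.frame `marker_a`, `marker_b`, `chromosome`, `distance_cM`,
#'   `r2`, with attribute `n_skipped_monomorphic`.
#' @export
ld_r2 <- function(G, max_distance_cM = Inf) {
  if (anyNA(G$dosage)) stop("genotypes contain missing values; impute first")
  if (is.null(G$map) || nrow(G$map) == 0) stop("no mapped markers")
  out <- list()
  n_skip <- 0L
  for (ch in unique(G$map$chrom)) {
    mp <- G$map[G$map$chrom == ch, ]
    mp <- mp[order(mp$pos_cM), ]
    X <- G$dosage[, mp$marker, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    poly <- sds > 0
    if (sum(poly) < 2) {
      npairs_all <- choose(nrow(mp), 2)
      n_skip <- n_skip + npairs_all
      next
    }
    pos <- mp$pos_cM
    idx <- which(poly)
    cc <- suppressWarnings(stats::cor(X[, idx, drop = FALSE]))^2
    ut <- which(upper.tri(cc), arr.ind = TRUE)
    a <- idx[ut[, 1]]; b <- idx[ut[, 2]]
    d <- abs(pos[a] - pos[b])
    keep <- d <= max_distance_cM
    # pairs involving monomorphic markers, within distance, are "skipped"
    if (any(!poly)) {
      mono <- which(!poly)
      all_pairs <- utils::combn(seq_len(nrow(mp)), 2)
      dall <- abs(pos[all_pairs[1, ]] - pos[all_pairs[2, ]])
      inv <- (all_pairs[1, ] %in% mono | all_pairs[2, ] %in% mono) &
        dall <= max_distance_cM
      n_skip <- n_skip + sum(inv)
    }
    if (any(keep))
      out[[ch]] <- data.frame(marker_a = mp$marker[a[keep]],
                              marker_b = mp$marker[b[keep]],
                              chromosome = ch,
                              distance_cM = d[keep],
                              r2 = cc[ut][keep],
                              stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(marker_a = character(), marker_b = character(),
               chromosome = character(), distance_cM = numeric(),
               r2 = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_skipped_monomorphic") <- n_skip
  res
}

#' Summarize LD decay over map-distance bins
#'
#' @param ld an [ld_r2()] table.
#' @param r2_threshold threshold for the "low-LD" fraction (default 0.2, the
#'   usual reporting convention for rapid LD decay).
#' @param dist_bins numeric vector of bin edges in cM.
#' @return data.frame per bin: `bin`, `dist_lo`, `dist_hi`, `n_pairs`,
#'   `frac_le_threshold`, `mean_r2` (NA for empty bins).
#' @export
ld_decay_summary <- function(ld, r2_threshold = 0.2,
                             dist_bins = c(0, 1, 2, 5, 10, 20, 50, Inf)) {
  if (nrow(ld) == 0) stop("empty LD table")
  bin <- cut(ld$distance_cM, dist_bins, right = FALSE, include.lowest = TRUE)
  lv <- levels(bin)
  res <- data.frame(
    bin = lv,
    dist_lo = dist_bins[-length(dist_bins)],
    dist_hi = dist_bins[-1],
    n_pairs = as.integer(table(bin)[lv]),
    frac_le_threshold = NA_real_,
    mean_r2 = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    r2s <- ld$r2[which(as.integer(bin) == i)]
    if (length(r2s)) {
      res$frac_le_threshold[i] <- mean(r2s <= r2_threshold)
      res$mean_r2[i] <- mean(r2s)
    }
  }
  res
}
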