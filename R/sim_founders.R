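#' Simulate founder haplotypes and a genetic map
#'
#' Draws a genetic map with markers spread uniformly over equally sized
#' chromosomes, an ancestral haplotype pool with per-SNP allele frequencies
#' targeted from Uniform(0.05, 0.95), and phased founder haplotypes as
#' recombinant mosaics of the ancestral pool. Founders stand in for the elite
#' parental pool of the breeding program: they are non-inbred and unrelated
#' in expectation (which is what the expected relationship matrix assumes for
#' pedigree founders), but because each haplotype is a mosaic of a limited
#' ancestral pool, nearby markers carry ancestral linkage disequilibrium that
#' decays with map distance — short-range LD persists across breeding cycles
#' while long-range LD is negligible, the pattern typical of an elite
#' outcrossing pool.
#'
#' The mosaic process switches to a random ancestral donor haplotype between
#' adjacent markers with probability `1 - exp(-d / mosaic_segment_cM)` for
#' map gap `d`, giving ancestral segments of about `mosaic_segment_cM` in
#' expectation.
#'
#' @param config a [sim_config()].
#' @return A `founder_set`: list with `h1`, `h2` (founders x SNPs binary
#'   haplotype matrices), `allele_freqs` (realized ancestral-pool
#'   frequencies), `ancestral` (the pool) and `map` (data.frame `marker`,
#'   `chrom`, `pos_cM`, sorted within chromosome).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  if (config$n_snps < config$n_chromosomes)
    stop("invalid configuration: n_snps < n_chromosomes")
  with_stream(config$seed, "founders", {
    n_f <- config$n_parents_total
    m <- config$n_snps
    n_anc <- config$n_ancestral_haplotypes
    seg <- config$mosaic_segment_cM
    # at least one marker per chromosome, remainder spread round-robin
    per_chr <- rep(config$n_snps %/% config$n_chromosomes, config$n_chromosomes)
    extra <- config$n_snps %% config$n_chromosomes
    if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
    chrom <- rep(paste0(seq_len(config$n_chromosomes), "R"), per_chr)
    pos <- unlist(lapply(per_chr, function(k)
      sort(stats::runif(k, 0, config$chrom_length_cM))))
    map <- data.frame(marker = sprintf("M%05d", seq_len(m)),
                      chrom = chrom, pos_cM = pos,
                      stringsAsFactors = FALSE)
    p_target <- stats::runif(m, 0.05, 0.95)
    anc <- matrix(stats::rbinom(n_anc * m, 1L, rep(p_target, each = n_anc)),
                  n_anc, m)
    # keep every SNP segregating in the pool
    mono <- which(colSums(anc) %in% c(0L, n_anc))
    if (length(mono))
      anc[cbind(sample.int(n_anc, length(mono), replace = TRUE), mono)] <-
        1L - anc[1, mono]
    mi <- map_index(map)
    mosaic <- function() {
      h <- integer(m)
      for (ch in mi) {
        gaps <- diff(ch$pos)
        sw <- c(TRUE, stats::runif(length(gaps)) < 1 - exp(-gaps / seg))
        seg_id <- cumsum(sw)
        donors <- sample.int(n_anc, max(seg_id), replace = TRUE)
        h[ch$idx] <- anc[cbind(donors[seg_id], ch$idx)]
      }
      h
    }
    h1 <- t(vapply(seq_len(n_f), function(i) mosaic(), integer(m)))
    h2 <- t(vapply(seq_len(n_f), function(i) mosaic(), integer(m)))
    rn <- sprintf("P%03d", seq_len(n_f))
    dimnames(h1) <- dimnames(h2) <- list(rn, map$marker)
    structure(list(h1 = h1, h2 = h2, allele_freqs = colMeans(anc),
                   ancestral = anc, map = map),
              class = "founder_set")
  })
}

# Precompute per-chromosome marker indices/positions for fast repeated meiosis.
map_index <- function(map) {
  chroms <- unique(map$chrom)
  lapply(chroms, function(ch) {
    idx <- which(map$chrom == ch)
    list(idx = idx, pos = map$pos_cM[idx],
         len = max(map$pos_cM[idx]))
  })
}

#' Sample one recombinant gamete from a pair of phased haplotypes
#'
#' Meiosis under Haldane's model: the number of crossovers per chromosome is
#' Poisson with mean `length_cM / 100`, breakpoint positions are uniform along
#' the chromosome, there is no interference, and chromosomes assort
#' independently (starting phase Bernoulli(1/2) per chromosome).
#'
#' @param h1,h2 the parent's two phased haplotype vectors (0/1 alleles).
#' @param map genetic map data.frame (`marker`, `chrom`, `pos_cM`) or a
#'   prebuilt index from the internal `map_index()`.
#' @param chrom_length_cM chromosome length used for the crossover rate;
#'   defaults to the largest mapped position per chromosome.
#' @return A binary gamete vector of the same length as the haplotypes.
#' @export
sample_gamete <- function(h1, h2, map, chrom_length_cM = NULL) {
  mi <- if (is.data.frame(map)) map_index(map) else map
  g <- h1
  for (ch in mi) {
    len <- if (is.null(chrom_length_cM)) ch$len else chrom_length_cM
    nx <- stats::rpois(1L, len / 100)
    phase <- stats::rbinom(1L, 1L, 0.5)
    if (nx > 0L) {
      breaks <- sort(stats::runif(nx, 0, len))
      phase <- (phase + findInterval(ch$pos, breaks)) %% 2L
    }
    take2 <- phase == 1L
    if (any(take2)) g[ch$idx[take2]] <- h2[ch$idx[take2]]
  }
  g
}
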