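#' Build trait architectures and calibrated variance components
#'
#' For each configured trait, QTL are sampled from the marker panel and
#' testcross substitution effects are drawn: polygenic traits get Gaussian
#' effects, oligogenic traits double-exponential effects. The testcross
#' genetic value of line i is `sum_j (dosage_ij / 2) * alpha_j` (mean gametic
#' transmission to the testcross progeny times the substitution effect).
#'
#' Architecture invariants are enforced on the per-QTL variance contribution
#' `c_j = alpha_j^2 var(dosage_j/2) / sum_k alpha_k^2 var(dosage_k/2)`:
#' polygenic traits are redrawn until no QTL exceeds 2 % of genetic variance;
#' for oligogenic traits the largest effect is inflated until it contributes
#' at least 12 %, representing a family-specific QTL of large effect.
#'
#' Variance components are calibrated to the target progeny-mean heritability:
#' the genotype x location.tester variance is `vc_gxl_ratio * sigma_g^2` and
#' the plot error variance solves
#' `h2 = sigma_g^2 / (sigma_g^2 + vbar_delta / 2)` under the balanced-design
#' approximation `vbar_delta = 2 (sigma_gxl^2 / L + sigma_e^2 / (L R))` with
#' `L` location.tester units and `R` replicates.
#'
#' @param config a [sim_config()].
#' @param G a [genotypes()] object of true dosages (the simulated lines).
#' @return Named list per trait with elements `qtl_idx`, `alpha`, `values`
#'   (named genetic values per line), `mean` (trait base mean), `sigma2_g`
#'   (realized genetic variance), `sigma2_gxlt`, `sigma2_lt`, `sigma2_block`,
#'   `sigma2_e`, `n_reps`.
#' @export
make_trait_architecture <- function(config, G) {
  traits <- sim_traits(config)
  base_means <- c(GDY = 85, PHT = 125, TKW = 35)
  L <- config$n_locations_per_cycle
  with_stream(config$seed, "architecture", {
    out <- lapply(traits, function(tr) {
      n_qtl <- config$qtl_counts[[tr]]
      model <- config$qtl_effect_model[[tr]]
      half <- G$dosage / 2
      v <- apply(half, 2, stats::var)
      # Oligogenic QTL are placed at low-frequency markers: the minor allele
      # then segregates in few families only, emulating the family-specific
      # large-effect QTL hypothesized for height- and kernel-weight-like
      # traits. Pedigree-expected relationships cannot track such alleles
      # across cycles, while markers can.
      candidates <- if (model == "oligogenic") {
        mafs <- pmin(p_line <- colMeans(G$dosage) / 2, 1 - p_line)
        low <- which(v > 1e-8 & mafs <= 0.2 & mafs >= 0.02)
        if (length(low) >= n_qtl) low else which(v > 1e-8)
      } else which(v > 1e-8)
      qtl <- sample(candidates, n_qtl)
      alpha <- if (model == "polygenic") stats::rnorm(n_qtl)
               else stats::rexp(n_qtl) * sample(c(-1, 1), n_qtl, replace = TRUE)
      if (model == "polygenic") {
        if (n_qtl < 50)
          stop("polygenic architecture needs >= 50 QTL to keep every ",
               "contribution below 2% of genetic variance")
        # cap per-QTL variance contributions at 2% (water-filling): raw
        # Gaussian draws always leave a few QTL above the cap
        w <- alpha^2 * v[qtl]
        for (it in 1:100) {
          cap <- w / sum(w) > 0.02
          if (!any(cap)) break
          w[cap] <- 0.02 * sum(w[!cap]) / (1 - 0.02 * sum(cap))
        }
        alpha <- sign(alpha) * sqrt(w / v[qtl])
      }
      contrib <- alpha^2 * v[qtl] / sum(alpha^2 * v[qtl])
      if (model == "oligogenic" && max(contrib) < 0.12) {
        j <- which.max(contrib)
        # inflate the top QTL so that c_j = 0.12 exactly
        rest <- sum(alpha[-j]^2 * v[qtl][-j])
        alpha[j] <- sign(alpha[j]) * sqrt(0.12 / 0.88 * rest / v[qtl][j])
      }
      g <- drop(half[, qtl, drop = FALSE] %*% alpha)
      sigma2_g <- stats::var(g)
      ratio <- if (length(config$vc_gxl_ratio) > 1) config$vc_gxl_ratio[[tr]]
               else config$vc_gxl_ratio
      sigma2_gxlt <- ratio * sigma2_g
      R <- config$n_reps[[tr]]
      h2 <- config$target_h2[[tr]]
      sigma2_e <- L * R * (sigma2_g * (1 - h2) / h2 - sigma2_gxlt / L)
      if (sigma2_e <= 0)
        stop(sprintf(
          "target h2 = %.2f for %s unattainable with gxl ratio %.2f at L = %d",
          h2, tr, ratio, L))
      bm <- if (tr %in% names(base_means)) base_means[[tr]] else 50
      list(qtl_idx = qtl,
           alpha = stats::setNames(alpha, colnames(G$dosage)[qtl]),
           values = stats::setNames(g, rownames(G$dosage)),
           mean = bm,
           sigma2_g = sigma2_g,
           sigma2_gxlt = sigma2_gxlt,
           sigma2_lt = sigma2_g,
           sigma2_block = 0.5 * sigma2_e,
           sigma2_e = sigma2_e,
           n_reps = R)
    })
    names(out) <- traits
    out
  })
}

#' Simulate plot-level testcross trials in alpha-lattice designs
#'
#' Each cycle is evaluated in its own set of locations, split between the
#' cycle's two testers (locations are confounded with testers, the default
#' allocation of the emulated program), so the environment unit is the
#' location.tester combination and every line is observed under both testers.
#' Within each location.tester and replicate, lines are randomized to
#' incomplete blocks of `block_size`. Plot values are
#' `cycle mean + genetic value + location.tester effect + g x location.tester
#' effect + replicate effect + block effect + plot error`, with variances from
#' [make_trait_architecture()]. Traits with `n_reps = 1` (TKW) are recorded
#' with a single replicate.
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_breeding_program()].
#' @param architecture result of [make_trait_architecture()].
#' @param traits subset of traits to simulate (default: all configured).
#' @return Plot records data.frame with columns `line_id`, `cycle`,
#'   `location`, `tester`, `loc_tester`, `replicate`, `block`, `trait`,
#'   `value`.
#' @export
simulate_testcross_trials <- function(config, sim, architecture,
                                      traits = sim_traits(config)) {
  missing_arch <- setdiff(traits, names(architecture))
  if (length(missing_arch))
    stop("missing architecture for trait(s): ", paste(missing_arch, collapse = ", "))
  ca <- sim$cycle_assignment
  L <- config$n_locations_per_cycle
  res <- list()
  for (tr in traits) {
    arch <- architecture[[tr]]
    res[[tr]] <- with_stream(config$seed, paste0("trials/", tr), {
      rows <- list()
      for (cy in seq_len(config$n_cycles)) {
        ids <- names(ca)[ca == cy]
        n <- length(ids)
        cycle_mean <- arch$mean + stats::rnorm(1, 0, 0.5 * sqrt(arch$sigma2_g))
        testers <- sprintf("T%d", ((cy - 1L) * config$n_testers_per_cycle) +
                             seq_len(config$n_testers_per_cycle))
        locs <- sprintf("Y%d_LOC%d", cy, seq_len(L))
        tester_of_loc <- rep(testers, length.out = L)
        lt_ids <- paste(locs, tester_of_loc, sep = ".")
        lt_eff <- stats::rnorm(L, 0, sqrt(arch$sigma2_lt))
        gxlt <- matrix(stats::rnorm(n * L, 0, sqrt(arch$sigma2_gxlt)), n, L,
                       dimnames = list(ids, lt_ids))
        n_blocks <- ceiling(n / config$block_size)
        for (l in seq_len(L)) {
          for (r in seq_len(arch$n_reps)) {
            ord <- sample(ids)
            blk <- rep(seq_len(n_blocks), each = config$block_size,
                       length.out = n)
            blk_eff <- stats::rnorm(n_blocks, 0, sqrt(arch$sigma2_block))
            rep_eff <- stats::rnorm(1, 0, sqrt(arch$sigma2_block / 2))
            val <- cycle_mean + arch$values[ord] + lt_eff[l] +
              gxlt[ord, l] + rep_eff + blk_eff[blk] +
              stats::rnorm(n, 0, sqrt(arch$sigma2_e))
            rows[[length(rows) + 1L]] <- data.frame(
              line_id = ord, cycle = cy, location = locs[l],
              tester = tester_of_loc[l], loc_tester = lt_ids[l],
              replicate = r, block = sprintf("B%02d", blk),
              trait = tr, value = unname(val), stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, rows)
    })
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mask genotype entries as missing
#'
#' Entries are masked independently at `missing_rate`; a configurable fraction
#' of SNPs receives an elevated rate so that the downstream missingness filter
#' has realistic targets. Masked entries become `NA`; the original values are
#' not recoverable from the output.
#'
#' @param G a [genotypes()] object.
#' @param missing_rate baseline per-entry missing probability in `[0, 1)`.
#' @param hotspot_fraction fraction of SNPs with elevated missingness.
#' @param hotspot_rate per-entry missing probability at hotspot SNPs (default
#'   eight times the baseline, capped at 0.5, so that chip-like failure
#'   hotspots actually exceed the usual 10 % missingness threshold).
#' @param seed integer seed.
#' @return A [genotypes()] object with `NA` at masked entries.
#' @export
corrupt_genotypes <- function(G, missing_rate, hotspot_fraction = 0.05,
                              hotspot_rate = min(0.5, 8 * missing_rate),
                              seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0 && hotspot_rate == 0) return(G)
  with_stream(seed, "corrupt", {
    d <- G$dosage
    m <- ncol(d)
    rate <- rep(missing_rate, m)
    n_hot <- round(hotspot_fraction * m)
    if (n_hot > 0) rate[sample(m, n_hot)] <- hotspot_rate
    mask <- matrix(stats::runif(length(d)) < rep(rate, each = nrow(d)),
                   nrow(d), m)
    d[mask] <- NA_real_
    genotypes(d, G$map)
  })
}
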