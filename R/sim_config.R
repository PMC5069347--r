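#' Configuration for the synthetic breeding-program generator
#'
#' Defines the dimensions and stochastic structure of the simulated multi-cycle
#' hybrid breeding program: how many selection cycles, how many S2 lines per
#' cycle, the parental pool and its overlap between consecutive cycles, the
#' genome (chromosome number/length, SNP count), the testcross trial layout
#' (testers, locations, replicates) and the genetic architecture and target
#' progeny-mean heritability of each trait.
#'
#' Defaults emulate the structure of a commercial hybrid rye program at desk
#' scale: 4 cycles x 260 S2 lines drawn from crosses of a pool of 203 parents
#' with 8-21 parents shared between consecutive cycles, about two lines per
#' cross (zero-truncated Poisson, capped at 24), a 7-chromosome genome of
#' 150 cM each carrying 2000 SNPs, 2 testers and 8 locations per cycle, and
#' three traits: a polygenic grain-yield-like trait (`GDY`, 200 QTL, target
#' h2 = 0.86, 2 replicates), an oligogenic plant-height-like trait (`PHT`,
#' 20 QTL, h2 = 0.91, 2 replicates) and an oligogenic thousand-kernel-weight-
#' like trait (`TKW`, 20 QTL, h2 = 0.90, 1 replicate).
#'
#' @param n_cycles number of selection cycles.
#' @param lines_per_cycle number of S2 lines sampled per cycle.
#' @param n_parents_total size of the overall parental pool.
#' @param common_parents_range integer length-2 vector, min/max number of
#'   parents shared between the parent sets of consecutive cycles.
#' @param mean_lines_per_cross mean of the zero-truncated Poisson number of S2
#'   lines derived per cross.
#' @param max_lines_per_cross cap on lines per cross.
#' @param n_chromosomes,chrom_length_cM,n_snps genome dimensions.
#' @param n_testers_per_cycle,n_locations_per_cycle trial layout; every line is
#'   tested under both testers, locations are split between testers so the
#'   location.tester combination is the environment unit.
#' @param n_reps named integer vector, replicates per trait.
#' @param target_h2 named numeric vector in (0,1], target progeny-mean
#'   heritability per trait.
#' @param qtl_counts named integer vector, QTL per trait.
#' @param qtl_effect_model named character vector, `"polygenic"` or
#'   `"oligogenic"` per trait.
#' @param vc_gxl_ratio ratio of the genotype x location.tester interaction
#'   variance to the genotypic variance (scalar, or named per trait).
#' @param n_ancestral_haplotypes size of the ancestral haplotype pool from
#'   which founder haplotypes are drawn as recombinant mosaics; a limited pool
#'   creates the short-range ancestral LD of an elite breeding pool.
#' @param mosaic_segment_cM expected ancestral-segment length of founder
#'   haplotypes (controls how fast ancestral LD decays with map distance).
#' @param block_size incomplete-block size of the alpha-lattice.
#' @param selfing_x selfing-generation count recorded in the pedigree for the
#'   S2 lines. The S2 genotype arises from two rounds of selfing, but the
#'   additive relationship matrix models the lines at `x = 1` (testcross seed
#'   taken from S1 plants); set `selfing_x = 2` to record the alternative
#'   convention.
#' @param seed integer root seed for all derived random streams.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cycles = 4,
                       lines_per_cycle = 260,
                       n_parents_total = 203,
                       common_parents_range = c(8L, 21L),
                       mean_lines_per_cross = 2,
                       max_lines_per_cross = 24,
                       n_chromosomes = 7,
                       chrom_length_cM = 150,
                       n_snps = 2000,
                       n_testers_per_cycle = 2,
                       n_locations_per_cycle = 8,
                       n_reps = c(GDY = 2L, PHT = 2L, TKW = 1L),
                       target_h2 = c(GDY = 0.86, PHT = 0.91, TKW = 0.90),
                       qtl_counts = c(GDY = 200L, PHT = 20L, TKW = 20L),
                       qtl_effect_model = c(GDY = "polygenic", PHT = "oligogenic",
                                            TKW = "oligogenic"),
                       vc_gxl_ratio = 0.5,
                       n_ancestral_haplotypes = 8,
                       mosaic_segment_cM = 20,
                       block_size = 26,
                       selfing_x = 1,
                       seed = 1L) {
  # accept YAML-style lists for the per-trait maps
  n_reps <- unlist(n_reps); target_h2 <- unlist(target_h2)
  qtl_counts <- unlist(qtl_counts); qtl_effect_model <- unlist(qtl_effect_model)
  common_parents_range <- unlist(common_parents_range)
  vc_gxl_ratio <- unlist(vc_gxl_ratio)
  cfg <- list(n_cycles = as.integer(n_cycles),
              lines_per_cycle = as.integer(lines_per_cycle),
              n_parents_total = as.integer(n_parents_total),
              common_parents_range = as.integer(common_parents_range),
              mean_lines_per_cross = mean_lines_per_cross,
              max_lines_per_cross = as.integer(max_lines_per_cross),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_cM = chrom_length_cM,
              n_snps = as.integer(n_snps),
              n_testers_per_cycle = as.integer(n_testers_per_cycle),
              n_locations_per_cycle = as.integer(n_locations_per_cycle),
              n_reps = n_reps,
              target_h2 = target_h2,
              qtl_counts = qtl_counts,
              qtl_effect_model = qtl_effect_model,
              vc_gxl_ratio = vc_gxl_ratio,
              n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
              mosaic_segment_cM = mosaic_segment_cM,
              block_size = as.integer(block_size),
              selfing_x = as.integer(selfing_x),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_cycles", "lines_per_cycle", "n_parents_total", "n_chromosomes",
              "n_snps", "n_testers_per_cycle", "n_locations_per_cycle",
              "block_size")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("invalid configuration: `", f, "` must be a count >= 1")
  if (cfg$n_snps < cfg$n_chromosomes)
    stop("invalid configuration: n_snps < n_chromosomes")
  if (cfg$mean_lines_per_cross <= 0)
    stop("invalid configuration: mean_lines_per_cross must be positive")
  if (cfg$chrom_length_cM <= 0)
    stop("invalid configuration: chrom_length_cM must be positive")
  if (any(cfg$target_h2 <= 0 | cfg$target_h2 > 1))
    stop("invalid configuration: target_h2 must lie in (0, 1]")
  if (length(cfg$common_parents_range) != 2L ||
      cfg$common_parents_range[1] > cfg$common_parents_range[2])
    stop("invalid configuration: common_parents_range must be (min, max)")
  if (cfg$common_parents_range[2] > parents_per_cycle(cfg))
    stop("invalid configuration: common-parent overlap exceeds the per-cycle parent pool")
  if (cfg$selfing_x < 0) stop("invalid configuration: selfing_x must be >= 0")
  traits <- names(cfg$target_h2)
  if (is.null(traits) || any(traits == ""))
    stop("invalid configuration: target_h2 must be named by trait")
  for (f in c("n_reps", "qtl_counts", "qtl_effect_model"))
    if (!all(traits %in% names(cfg[[f]])))
      stop("invalid configuration: `", f, "` must cover all traits in target_h2")
  if (!all(cfg$qtl_effect_model %in% c("polygenic", "oligogenic")))
    stop("invalid configuration: qtl_effect_model must be polygenic/oligogenic")
  if (any(cfg$qtl_counts > cfg$n_snps))
    stop("invalid configuration: more QTL than SNPs")
  invisible(cfg)
}

#' Traits declared in a simulation configuration
#' @param cfg a `sim_config`.
#' @export
sim_traits <- function(cfg) names(cfg$target_h2)

# Per-cycle parent-pool size implied by the total pool, the number of cycles
# and the minimum common-parent overlap (the minimum guarantees that every
# cycle can recruit enough parents outside the previous cycle's pool).
parents_per_cycle <- function(cfg) {
  k_min <- cfg$common_parents_range[1]
  m <- as.integer(floor((cfg$n_parents_total + (cfg$n_cycles - 1) * k_min) /
                          cfg$n_cycles))
  m <- min(m, as.integer(floor((cfg$n_parents_total + k_min) / 2)))
  max(2L, m)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d cycles x %d S2 lines; %d parents (overlap %d-%d)\n",
              x$n_cycles, x$lines_per_cycle, x$n_parents_total,
              x$common_parents_range[1], x$common_parents_range[2]))
  cat(sprintf("  genome: %d SNPs on %d chromosomes x %.0f cM\n",
              x$n_snps, x$n_chromosomes, x$chrom_length_cM))
  cat(sprintf("  trials: %d testers, %d locations per cycle\n",
              x$n_testers_per_cycle, x$n_locations_per_cycle))
  cat("  traits:", paste(sprintf("%s(h2=%.2f,%s)", sim_traits(x), x$target_h2,
                                 x$qtl_effect_model[sim_traits(x)]),
                         collapse = " "), "\n")
  invisible(x)
}
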