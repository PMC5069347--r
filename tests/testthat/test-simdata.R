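test_that("founder simulation places markers on every chromosome and is seed-deterministic", {
  cfg <- tiny_config(n_snps = 7, n_chromosomes = 7, qtl_counts = c(GDY = 5L),
                     qtl_effect_model = c(GDY = "oligogenic"))
  f <- simulate_founders(cfg)
  expect_setequal(unique(f$map$chrom), paste0(1:7, "R"))
  expect_true(all(table(f$map$chrom) >= 1))
  expect_true(all(diff(f$map$pos_cM[f$map$chrom == "1R"]) >= 0))

  f2 <- simulate_founders(cfg)
  expect_identical(f, f2)
  f3 <- simulate_founders(tiny_config(seed = 8, n_snps = 7, n_chromosomes = 7,
                                      qtl_counts = c(GDY = 5L),
                                      qtl_effect_model = c(GDY = "oligogenic")))
  expect_false(identical(f$h1, f3$h1))

  expect_error(simulate_founders(tiny_config(n_snps = 3)),
               "n_snps < n_chromosomes")
})

test_that("founder haplotype frequencies match their sampling frequencies (binomial bound)", {
  cfg <- tiny_config(n_parents_total = 5000, lines_per_cycle = 5,
                     common_parents_range = c(2L, 3L), n_snps = 20,
                     qtl_counts = c(GDY = 10L),
                     qtl_effect_model = c(GDY = "oligogenic"))
  f <- simulate_founders(cfg)
  obs <- (colMeans(f$h1) + colMeans(f$h2)) / 2
  # 10,000 haplotypes per SNP: 4 sigma < 0.02
  expect_true(max(abs(obs - f$allele_freqs)) < 0.02)
})

test_that("meiosis obeys Haldane recombination fractions", {
  map <- data.frame(marker = c("a", "b"), chrom = "1R", pos_cM = c(0, 100))
  h1 <- c(1L, 1L); h2 <- c(0L, 0L)
  set.seed(1)
  gam <- replicate(1e4, sample_gamete(h1, h2, map, chrom_length_cM = 100))
  rec <- mean(gam[1, ] != gam[2, ])
  expect_equal(rec, 0.5 * (1 - exp(-2)), tolerance = 0.05)

  # co-located loci never recombine
  map0 <- data.frame(marker = c("a", "b"), chrom = "1R", pos_cM = c(25, 25))
  gam0 <- replicate(1e3, sample_gamete(h1, h2, map0, chrom_length_cM = 100))
  expect_true(all(gam0[1, ] == gam0[2, ]))

  # identical parental haplotypes pass through unchanged
  same <- replicate(20, sample_gamete(h1, h1, map, chrom_length_cM = 100))
  expect_true(all(same == h1))
})

test_that("breeding program has the configured size, overlap and pedigree structure", {
  cfg <- tiny_config()
  sim <- simulate_breeding_program(cfg)
  lines <- names(sim$cycle_assignment)
  expect_length(lines, cfg$n_cycles * cfg$lines_per_cycle)
  expect_equal(unname(table(sim$cycle_assignment)),
               rep(cfg$lines_per_cycle, cfg$n_cycles),
               ignore_attr = TRUE)
  # pedigree: lines + their parents, topologically valid
  expect_silent(validate_pedigree(sim$pedigree))
  expect_true(all(lines %in% sim$pedigree$id))
  # consecutive parent pools share the configured number of parents
  for (cy in 2:cfg$n_cycles) {
    k <- length(intersect(sim$parent_pools[[cy - 1]], sim$parent_pools[[cy]]))
    expect_gte(k, cfg$common_parents_range[1])
    expect_lte(k, cfg$common_parents_range[2])
  }
  # determinism
  sim2 <- simulate_breeding_program(cfg)
  expect_identical(sim$genotypes$dosage, sim2$genotypes$dosage)
  expect_identical(sim$pedigree, sim2$pedigree)
})

test_that("S2 alleles are Mendelian-consistent with founder genotypes", {
  cfg <- tiny_config(lines_per_cycle = 20)
  sim <- simulate_breeding_program(cfg)
  f <- sim$founders
  ped <- sim$pedigree
  lines <- ped[!is.na(ped$parent1), ]
  for (i in seq_len(nrow(lines))) {
    d <- sim$genotypes$dosage[lines$id[i], ]
    p1 <- match(lines$parent1[i], rownames(f$h1))
    p2 <- match(lines$parent2[i], rownames(f$h1))
    # the S2 plant's two alleles are copies of the F1's pair (one allele per
    # parent), so the dosage is bounded by twice the extreme parental alleles
    max_alt <- 2 * pmax(f$h1[p1, ], f$h2[p1, ], f$h1[p2, ], f$h2[p2, ])
    min_alt <- 2 * pmin(f$h1[p1, ], f$h2[p1, ], f$h1[p2, ], f$h2[p2, ])
    expect_true(all(d <= max_alt & d >= min_alt))
  }
})

test_that("S2 residual heterozygosity matches the gene-drop expectation", {
  # At a locus with founder allele frequency p, an F1 of two independent
  # founders is heterozygous with probability 2p(1-p); each single-seed
  # descent generation halves it, so S2 heterozygosity is 2p(1-p)/4
  # (0.125 at p = 0.5). Oracle: direct gene-drop over many loci.
  set.seed(99)
  n_loci <- 2e4
  f1 <- cbind(rbinom(n_loci, 1, .5), rbinom(n_loci, 1, .5))
  self_once <- function(h) {
    cbind(h[cbind(seq_len(nrow(h)), sample(1:2, nrow(h), TRUE))],
          h[cbind(seq_len(nrow(h)), sample(1:2, nrow(h), TRUE))])
  }
  s2 <- self_once(self_once(f1))
  oracle_het <- mean(s2[, 1] != s2[, 2])
  expect_equal(oracle_het, 0.125, tolerance = 0.02)

  cfg <- tiny_config(n_snps = 500)
  sim <- simulate_breeding_program(cfg)
  p <- sim$founders$allele_freqs
  near_half <- which(abs(p - 0.5) < 0.1)
  het <- mean(sim$genotypes$dosage[, near_half] == 1)
  expect_lt(abs(het - oracle_het), 0.03)
})

test_that("plot records satisfy the trial-design invariants", {
  cfg <- tiny_config(n_reps = c(GDY = 2L, TKW = 1L),
                     target_h2 = c(GDY = 0.86, TKW = 0.90),
                     qtl_counts = c(GDY = 60L, TKW = 20L),
                     qtl_effect_model = c(GDY = "polygenic",
                                          TKW = "oligogenic"),
                     vc_gxl_ratio = 0.3)
  sim <- simulate_breeding_program(cfg)
  arch <- make_trait_architecture(cfg, sim$genotypes)
  plots <- simulate_testcross_trials(cfg, sim, arch)
  # every line appears under exactly 2 testers within its cycle
  tt <- tapply(plots$tester, plots$line_id, function(x) length(unique(x)))
  expect_true(all(tt == 2))
  # each line once per replicate within a location.tester
  expect_equal(anyDuplicated(plots[, c("trait", "loc_tester", "replicate",
                                       "line_id")]), 0L)
  # single-replicate trait
  expect_equal(max(plots$replicate[plots$trait == "TKW"]), 1L)
  expect_equal(max(plots$replicate[plots$trait == "GDY"]), 2L)
  # missing architecture errors
  expect_error(simulate_testcross_trials(cfg, sim, arch["GDY"],
                                         traits = c("GDY", "TKW")),
               "missing architecture")
})

test_that("trait architectures respect the polygenic/oligogenic contribution bounds", {
  cfg <- tiny_config(n_reps = c(GDY = 2L, PHT = 2L),
                     target_h2 = c(GDY = 0.86, PHT = 0.91),
                     qtl_counts = c(GDY = 60L, PHT = 20L),
                     qtl_effect_model = c(GDY = "polygenic",
                                          PHT = "oligogenic"),
                     vc_gxl_ratio = 0.3)
  sim <- simulate_breeding_program(cfg)
  arch <- make_trait_architecture(cfg, sim$genotypes)
  contrib <- function(a) {
    v <- apply(sim$genotypes$dosage[, a$qtl_idx] / 2, 2, var)
    a$alpha^2 * v / sum(a$alpha^2 * v)
  }
  expect_lte(max(contrib(arch$GDY)), 0.02 + 1e-10)
  expect_gte(max(contrib(arch$PHT)), 0.10)
})

test_that("genotype corruption masks at the requested rate and hides originals", {
  G <- random_genotypes(1000, 1000, seed = 3)
  Gm <- corrupt_genotypes(G, 0.05, hotspot_fraction = 0, seed = 5)
  expect_lt(abs(mean(is.na(Gm$dosage)) - 0.05), 0.001)
  # observed entries untouched
  obs <- !is.na(Gm$dosage)
  expect_identical(Gm$dosage[obs], G$dosage[obs])
  # rate 0 leaves the matrix unchanged
  expect_identical(corrupt_genotypes(G, 0), G)
  # hotspot SNPs give the missingness filter real targets
  Gh <- corrupt_genotypes(G, 0.05, hotspot_fraction = 0.1, hotspot_rate = 0.3,
                          seed = 5)
  expect_gt(sum(missing_fraction(Gh) > 0.15), 0)
})

test_that("LD decays with map distance in simulated programs (sign check)", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- tiny_config(seed = 100 + s, n_snps = 200, lines_per_cycle = 30)
    sim <- simulate_breeding_program(cfg)
    ld <- ld_r2(sim$genotypes)
    near <- ld$r2[ld$distance_cM < 1]
    far <- ld$r2[ld$distance_cM > 20]
    if (length(near) && length(far) && mean(near) > mean(far))
      wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
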