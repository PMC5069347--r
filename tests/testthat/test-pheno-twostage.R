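test_that("Grubbs test removes a planted gross outlier and nothing from clean data", {
  set.seed(21)
  r <- rnorm(100)
  r <- c(r, 10)
  out <- detect_outliers_grubbs(r, alpha = 0.05)
  expect_equal(out[1], 101L)
  # critical value from the t-distribution is in the published ballpark
  expect_equal(grubbs_critical(101, 0.05), 3.38, tolerance = 0.01)
  # constant residuals: guarded, none removed
  expect_length(detect_outliers_grubbs(rep(1, 20)), 0)
  # alpha -> 0: critical value approaches its (n-1)/sqrt(n) bound, so a
  # clean sample yields no removals
  expect_length(detect_outliers_grubbs(r[1:100], alpha = 1e-12), 0)
  # too few residuals
  expect_warning(out2 <- detect_outliers_grubbs(c(1, 2)), "fewer than 3")
  expect_length(out2, 0)
})

make_lattice_plots <- function(n_g = 6, n_rep = 2, n_blk = 3, sd_blk = 1,
                               sd_e = 0.5, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_g, 50, 3)
  rows <- list()
  for (r in seq_len(n_rep)) {
    ord <- sample(n_g)
    blk <- rep(seq_len(n_blk), each = n_g / n_blk)
    beff <- rnorm(n_blk, 0, sd_blk)
    for (i in seq_len(n_g)) {
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = sprintf("G%d", ord[i]), cycle = 1, location = "LOC1",
        tester = "T1", loc_tester = "LOC1.T1", replicate = r,
        block = sprintf("B%d", blk[i]), trait = "GDY",
        value = g[ord[i]] + (r - 1) * 0.7 + beff[blk[i]] + rnorm(1, 0, sd_e))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "true_g") <- g
  out
}

test_that("stage-1 means equal arithmetic plot means under balance with no block effects", {
  plots <- make_lattice_plots(sd_blk = 0, sd_e = 0.3, seed = 2)
  am <- stage1_adjusted_means(plots, "LOC1", "T1", "GDY",
                              outlier_alpha = NULL)
  arith <- tapply(plots$value, plots$line_id, mean)
  expect_equal(am$blue, as.vector(arith[am$line_id]), tolerance = 1e-6)
  expect_true(all(am$se > 0))
})

test_that("stage-1 adjusted means solve the generalized-least-squares normal equations", {
  plots <- make_lattice_plots(sd_blk = 2, sd_e = 0.5, seed = 3)
  fitted <- ryegp:::fit_lattice(plots)
  am <- ryegp:::adjusted_means_from_fit(fitted, plots)
  # oracle: explicit GLS with V assembled from the fitted variance components
  vc <- as.data.frame(lme4::VarCorr(fitted))
  s2b <- vc$vcov[vc$grp == "blk"]; s2e <- vc$vcov[vc$grp == "Residual"]
  blk <- factor(paste(plots$replicate, plots$block, sep = ":"))
  Zb <- model.matrix(~0 + blk)
  V <- s2e * diag(nrow(plots)) + s2b * tcrossprod(Zb)
  gf <- factor(plots$line_id); rf <- factor(plots$replicate)
  X <- cbind(model.matrix(~0 + gf), model.matrix(~rf)[, -1, drop = FALSE])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% plots$value)
  oracle <- beta[seq_len(nlevels(gf))] + mean(c(0, beta[-seq_len(nlevels(gf))]))
  expect_equal(am$blue[match(levels(gf), am$line_id)], unname(oracle),
               tolerance = 1e-8)
})

test_that("single-replicate trials get block-adjusted plot values", {
  set.seed(11)
  n_g <- 40; n_blk <- 4
  g <- rnorm(n_g, 30, 2)
  blk <- rep(seq_len(n_blk), each = n_g / n_blk)
  beff <- c(-3, -1, 1, 3)
  plots <- data.frame(line_id = sprintf("G%02d", 1:n_g), cycle = 1,
                      location = "LOC1", tester = "T1",
                      loc_tester = "LOC1.T1", replicate = 1,
                      block = sprintf("B%d", blk), trait = "TKW",
                      value = g + beff[blk] + rnorm(n_g, 0, 0.3))
  am <- stage1_adjusted_means(plots, "LOC1", "T1", "TKW",
                              outlier_alpha = NULL)
  # block adjustment recovers the genetic values better than raw plot values
  expect_gt(cor(am$blue, g), cor(plots$value, g))
  expect_lt(mean((am$blue - mean(am$blue) - (g - mean(g)))^2),
            mean((plots$value - mean(plots$value) - (g - mean(g)))^2))
  expect_equal(length(unique(am$se)), 1L)   # common per-trial standard error
  expect_true(all(am$se > 0))
})

test_that("stage-1 rejects malformed trials", {
  plots <- make_lattice_plots(seed = 4)
  expect_error(stage1_adjusted_means(rbind(plots, plots[1, ]),
                                     "LOC1", "T1", "GDY"), "duplicate|twice")
  expect_error(stage1_adjusted_means(plots, "NOPE", "T1", "GDY"),
               "no plot records")
})

make_stage2_means <- function(n_g = 20, n_lt = 4, sd_lt = 1, sd_gxlt = 0.5,
                              se = 0.3, seed = 5) {
  set.seed(seed)
  g <- rnorm(n_g, 10, 2)
  d <- expand.grid(line_id = sprintf("G%02d", seq_len(n_g)),
                   loc_tester = sprintf("LT%d", seq_len(n_lt)),
                   stringsAsFactors = FALSE)
  lt <- rnorm(n_lt, 0, sd_lt)
  d$blue <- g[match(d$line_id, sprintf("G%02d", 1:n_g))] +
    lt[match(d$loc_tester, sprintf("LT%d", 1:n_lt))] +
    rnorm(nrow(d), 0, sd_gxlt)
  d$se <- rep(se, length.out = nrow(d))
  d$trait <- "GDY"; d$cycle <- 1
  attr(d, "true_g") <- g
  d
}

test_that("stage-2 collapses to stage-1 means for a single trial and to their average for balanced trials", {
  m1 <- make_stage2_means(n_lt = 1)
  f1 <- stage2_blues(m1)
  expect_true(f1$single_lt)
  expect_equal(f1$blues$blue[match(m1$line_id, f1$blues$line_id)], m1$blue,
               tolerance = 1e-8)

  m2 <- make_stage2_means(n_lt = 2, sd_gxlt = 1e-4, sd_lt = 1e-4)
  f2 <- stage2_blues(m2)
  avg <- tapply(m2$blue, m2$line_id, mean)
  expect_equal(f2$blues$blue, as.vector(avg[f2$blues$line_id]), tolerance = 1e-5)
})

test_that("equal weights coincide with the unweighted stage-2 fit", {
  m <- make_stage2_means(n_lt = 4, sd_gxlt = 0.7, seed = 6)
  f_a <- stage2_blues(m)
  m$se <- m$se * 3  # uniform rescaling must not move the BLUEs
  f_b <- stage2_blues(m)
  expect_equal(f_a$blues$blue, f_b$blues$blue, tolerance = 1e-8)
})

test_that("stage-2 REML recovers generating variance components", {
  rel_err <- function(est, true) abs(est - true) / true
  errs <- sapply(1:10, function(s) {
    m <- simulated_adjusted_means(n_lines = 260, n_lt = 8, var_g = 15,
                                  var_lt = 10, var_gxlt = 7.5, seed = s)
    v <- stage2_varcomp(m)
    c(g = rel_err(v$var_g, 15), gxlt = rel_err(v$var_gxlt, 7.5))
  })
  expect_lt(median(errs["g", ]), 0.25)
  expect_lt(median(errs["gxlt", ]), 0.25)
})

test_that("stage-2 detects no genetic signal at the boundary and scales with the data", {
  m <- simulated_adjusted_means(n_lines = 120, n_lt = 6, var_g = 0,
                                var_lt = 5, var_gxlt = 3, seed = 7)
  v0 <- stage2_varcomp(m)
  expect_lt(v0$var_g, 1)

  m2 <- simulated_adjusted_means(n_lines = 60, n_lt = 4, seed = 8)
  v1 <- stage2_varcomp(m2)
  m2$blue <- 2 * m2$blue; m2$se <- 2 * m2$se
  v2 <- stage2_varcomp(m2)
  expect_equal(v2$var_g, 4 * v1$var_g, tolerance = 1e-3)
  expect_equal(v2$mean_vd, 4 * v1$mean_vd, tolerance = 1e-3)
  expect_equal(v2$h2, v1$h2, tolerance = 1e-3)
})

test_that("stage-2 BLUEs track true genetic values at the heritability-implied precision", {
  r2s <- sapply(1:10, function(s) {
    m <- simulated_adjusted_means(n_lines = 100, n_lt = 4, var_g = 15,
                                  var_lt = 10, var_gxlt = 7.5,
                                  se2_range = c(1, 2), seed = 20 + s)
    f <- stage2_blues(m)
    v <- stage2_varcomp(m)
    g <- attr(m, "true_g")
    c(r2 = cor(f$blues$blue, g[f$blues$line_id])^2, h2 = v$h2)
  })
  expect_equal(mean(r2s["r2", ]), mean(r2s["h2", ]), tolerance = 0.12)
})

test_that("progeny-mean heritability follows its closed form and monotonicities", {
  expect_equal(heritability(4, 4), 4 / 6)
  expect_equal(heritability(0, 1), 0)
  expect_equal(heritability(5, 1e-12), 1, tolerance = 1e-10)
  expect_error(heritability(4, 0), "positive")
  expect_error(heritability(-1, 1))
  # strictly increasing in var_g, decreasing in mean_vd
  h <- sapply(seq(0.5, 10, by = 0.5), heritability, mean_vd = 2)
  expect_true(all(diff(h) > 0))
  h2 <- sapply(seq(0.5, 10, by = 0.5), function(v) heritability(4, v))
  expect_true(all(diff(h2) < 0))
})

test_that("the full two-stage pipeline returns plot means for balanced noise-free designs", {
  cfg <- tiny_config(lines_per_cycle = 12, n_cycles = 1, n_snps = 100,
                     n_locations_per_cycle = 2, block_size = 4,
                     qtl_counts = c(GDY = 50L), vc_gxl_ratio = 0.25)
  sim <- simulate_breeding_program(cfg)
  arch <- make_trait_architecture(cfg, sim$genotypes)
  # zero block / trial / interaction variance: only plot error remains
  arch$GDY$sigma2_block <- 0
  arch$GDY$sigma2_lt <- 0
  arch$GDY$sigma2_gxlt <- 0
  plots <- simulate_testcross_trials(cfg, sim, arch)
  ts <- two_stage_pipeline(plots, outlier_alpha = NULL)
  pm <- tapply(plots$value, plots$line_id, mean)
  expect_lt(max(abs(ts$blues$blue - pm[ts$blues$line_id])), 0.05)

  # near-noise-free: BLUEs equal genetic values up to a constant, h2 ~ 1
  arch$GDY$sigma2_e <- 1e-6
  plots2 <- simulate_testcross_trials(cfg, sim, arch)
  ts2 <- two_stage_pipeline(plots2, outlier_alpha = NULL)
  g <- arch$GDY$values[ts2$blues$line_id]
  expect_lt(max(abs(ts2$blues$blue - g - mean(ts2$blues$blue - g))), 1e-3)
  expect_gt(ts2$varcomp$h2, 0.999)
})
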