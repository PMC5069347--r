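# Fake 4-cycle program: fold-plan logic needs only ids and cycles.
fake_assignment <- function(lines_per_cycle = 260, n_cycles = 4) {
  ids <- unlist(lapply(seq_len(n_cycles), function(cy)
    sprintf("C%d_L%03d", cy, seq_len(lines_per_cycle))))
  stats::setNames(rep(seq_len(n_cycles), each = lines_per_cycle), ids)
}

test_that("fold plans partition each cycle into equal validation folds", {
  ca <- fake_assignment()
  plan <- make_folds(ca, n_reps = 10, n_folds = 5, seed = 3)
  for (r in c(1, 10)) {
    prep <- plan[plan$replicate == r, ]
    for (cy in 1:4) {
      pc <- prep[prep$cycle == cy, ]
      expect_setequal(pc$line_id, names(ca)[ca == cy])
      expect_equal(unname(table(pc$fold)), rep(52L, 5), ignore_attr = TRUE)
    }
  }
  # reproducible from the seed; different seeds give different plans
  expect_identical(plan, make_folds(ca, 10, 5, seed = 3))
  expect_false(identical(plan$line_id, make_folds(ca, 10, 5, seed = 4)$line_id))
  expect_error(make_folds(ca[1:3], n_folds = 5), "fewer lines than folds")
  expect_message(make_folds(fake_assignment(11, 1), n_reps = 1, n_folds = 5),
                 "differ by")
})

test_that("calibration sets have the specified sizes, sources and exclusions", {
  ca <- fake_assignment()
  plan <- make_folds(ca, n_reps = 2, n_folds = 5, seed = 9)
  vs <- plan$line_id[plan$replicate == 1 & plan$cycle == 2 & plan$fold == 3]

  cs1 <- build_cs(list(name = "CV1", vs_cycle = 2, cs_cycles = 2), plan, 1, 3)
  expect_length(cs1, 208)
  expect_length(intersect(cs1, vs), 0)
  expect_true(all(ca[cs1] == 2))

  # CV2.3: equal numbers per calibration cycle, none from the validation cycle
  sc23 <- list(name = "CV2.3", vs_cycle = 2, cs_cycles = c(1, 3, 4),
               n_cs = 624)
  cs23 <- build_cs(sc23, plan, 1, 3)
  expect_equal(unname(table(ca[cs23])), rep(208L, 3), ignore_attr = TRUE)
  expect_false(any(ca[cs23] == 2))

  # CV3 at maximum size: 208 per cycle; the validation cycle contributes
  # exactly its four non-validation folds
  sc3 <- list(name = "CV3", vs_cycle = 2, cs_cycles = 1:4, n_cs = 832)
  cs3 <- build_cs(sc3, plan, 1, 3)
  expect_length(cs3, 832)
  expect_equal(unname(table(ca[cs3])), rep(208L, 4), ignore_attr = TRUE)
  expect_length(intersect(cs3, vs), 0)
  expect_setequal(cs3[ca[cs3] == 2], setdiff(names(ca)[ca == 2], vs))

  # smaller CV3 sizes subsample but keep equal representation
  cs3s <- build_cs(list(name = "CV3", vs_cycle = 2, cs_cycles = 1:4,
                        n_cs = 416), plan, 1, 3)
  expect_equal(unname(table(ca[cs3s])), rep(104L, 4), ignore_attr = TRUE)

  # CV2.2: two calibration cycles, half the quota each
  cs22 <- build_cs(list(name = "CV2.2", vs_cycle = 2, cs_cycles = c(1, 4),
                        n_cs = 208), plan, 1, 3)
  expect_equal(unname(table(ca[cs22])), rep(104L, 2), ignore_attr = TRUE)
  expect_setequal(unique(ca[cs22]), c(1, 4))

  expect_error(build_cs(list(name = "CV2.1", vs_cycle = 2, cs_cycles = 2,
                             n_cs = 208), plan, 1, 3), "exclude")
  expect_error(build_cs(list(name = "CV2.1", vs_cycle = 2, cs_cycles = 3,
                             n_cs = 300), plan, 1, 3), "available")
  # reproducibility of the subsampling stream
  expect_identical(build_cs(sc23, plan, 1, 3), build_cs(sc23, plan, 1, 3))
})

test_that("heritability-corrected accuracy follows its formula and guards", {
  expect_equal(accuracy(0.5, 0.64), 0.625)
  expect_equal(accuracy(0, 0.5), 0)
  expect_equal(accuracy(0.7, 1), 0.7)
  expect_error(accuracy(0.5, 0), "h2_v")
  expect_error(accuracy(0.5, 1.2), "h2_v")
  expect_warning(accuracy(0.9, 0.5), "exceeds 1.1")
})

# Small but structured study used by the engine-level tests: noise-free
# phenotypes and a causal-marker kernel make prediction nearly exact.
noiseless_study <- function(seed = 13, n_cycles = 2, lines_per_cycle = 60) {
  cfg <- tiny_config(seed = seed, n_cycles = n_cycles,
                     lines_per_cycle = lines_per_cycle, n_snps = 300,
                     qtl_counts = c(GDY = 20L),
                     qtl_effect_model = c(GDY = "oligogenic"))
  sim <- simulate_breeding_program(cfg)
  arch <- make_trait_architecture(cfg, sim$genotypes)
  g <- arch$GDY$values
  ids <- names(sim$cycle_assignment)
  blues <- data.frame(line_id = ids, cycle = sim$cycle_assignment[ids],
                      trait = "GDY", blue = unname(g[ids]),
                      stringsAsFactors = FALSE)
  Gq <- genotypes(sim$genotypes$dosage[ids, arch$GDY$qtl_idx])
  U <- realized_kinship(Gq) + diag(1e-6, length(ids))
  h2 <- data.frame(cycle = rep(seq_len(n_cycles), each = 1), trait = "GDY",
                   h2 = 1)
  list(cfg = cfg, sim = sim, blues = blues, U = U, h2 = h2, ids = ids,
       qtl_idx = arch$GDY$qtl_idx)
}

test_that("the CV engine reuses validation sets and predicts nearly perfectly without noise", {
  ns <- noiseless_study()
  plan <- make_folds(ns$sim$cycle_assignment, n_reps = 2, n_folds = 5,
                     seed = 21)
  res <- run_cv(ns$blues, list(GBLUP = ns$U), ns$h2, plan,
                scenarios = c("CV1", "CV2.1"))
  expect_s3_class(res, "cv_result")
  # h2 = 1: accuracy equals predictive ability
  expect_equal(res$accuracy, res$rho)
  # noiseless causal-kernel within-cycle prediction is nearly exact
  expect_gt(mean(res$accuracy[res$scenario == "CV1"]), 0.95)
  # identical folds imply identical n_cs across scenarios for the same fold
  expect_true(all(res$n_cs[res$scenario == "CV1"] == 48))
  # every scenario x replicate x fold x cycle key appears exactly once per
  # trait/model/cs-combination
  expect_equal(anyDuplicated(res[, c("scenario", "model", "trait",
                                     "replicate", "fold", "vs_cycle",
                                     "cs_cycles", "n_cs")]), 0L)
})

test_that("validation sets are byte-identical across scenarios and kernels", {
  ca <- fake_assignment(30, 3)
  plan <- make_folds(ca, n_reps = 2, n_folds = 5, seed = 5)
  # VS is defined by (replicate, fold, cycle) in the plan alone; build_cs for
  # any scenario never touches it
  for (sc in list(list(name = "CV1", vs_cycle = 1, cs_cycles = 1),
                  list(name = "CV2.1", vs_cycle = 1, cs_cycles = 2, n_cs = 24),
                  list(name = "CV3", vs_cycle = 1, cs_cycles = 1:3, n_cs = 72))) {
    cs <- build_cs(sc, plan, 2, 4)
    vs <- plan$line_id[plan$replicate == 2 & plan$cycle == 1 & plan$fold == 4]
    expect_length(intersect(cs, vs), 0)
  }
})

test_that("degenerate validation responses are recorded as missing with a reason", {
  ns <- noiseless_study()
  blues_const <- ns$blues
  blues_const$blue <- 1  # constant observations
  plan <- make_folds(ns$sim$cycle_assignment, n_reps = 1, n_folds = 5,
                     seed = 2)
  res <- run_cv(blues_const, list(GBLUP = ns$U), ns$h2, plan,
                scenarios = "CV1")
  expect_true(all(is.na(res$rho)))
  expect_true(all(grepl("degenerate", res$note)))

  # missing heritability for a validation cycle errors
  expect_error(run_cv(ns$blues, list(GBLUP = ns$U), ns$h2[1, , drop = FALSE],
                      plan, scenarios = "CV1"), "missing heritability")
})

test_that("paired Fisher-Z comparison detects equal and unequal model results", {
  ns <- noiseless_study()
  plan <- make_folds(ns$sim$cycle_assignment, n_reps = 2, n_folds = 5,
                     seed = 31)
  # weaker competitor: kernel from the non-causal markers only (family
  # relatedness without the QTL signal)
  d <- ns$sim$genotypes$dosage[ns$ids, ]
  U_weak <- realized_kinship(genotypes(
    d[, setdiff(seq_len(ncol(d)), ns$qtl_idx), drop = FALSE])) +
    diag(1e-6, length(ns$ids))
  res <- run_cv(ns$blues, list(GBLUP = ns$U, WEAK = U_weak), ns$h2, plan,
                scenarios = "CV1")
  a <- res[res$model == "GBLUP", ]
  b <- res[res$model == "WEAK", ]
  # self-comparison: t = 0, p = 1
  same <- compare_models(a, a)
  expect_equal(same$t, rep(0, nrow(same)))
  expect_equal(same$p, rep(1, nrow(same)))
  # informative kernel vs uninformative kernel: strongly significant
  cmp <- compare_models(a, b)
  expect_true(all(cmp$p < 0.05))
  expect_true(all(cmp$mean_z_diff > 0))
  # Fisher-Z is atanh: z(0.5) = log(3)/2
  expect_equal(atanh(0.5), 0.5 * log(3))
  expect_error(compare_models(a, b[-1, ]), "identical")
})

test_that("summaries aggregate by scenario and preserve the cycle-matrix layout", {
  ns <- noiseless_study()
  plan <- make_folds(ns$sim$cycle_assignment, n_reps = 2, n_folds = 5,
                     seed = 41)
  res <- run_cv(ns$blues, list(GBLUP = ns$U), ns$h2, plan,
                scenarios = c("CV1", "CV2.1"))
  sm <- summarize_cv(res)
  expect_true(all(c("summary", "by_replicate", "fig3_matrix", "fig4_pairs",
                    "fig5_boxdata") %in% names(sm)))
  # single-row aggregate equals the value itself
  one <- summarize_cv(res[1, , drop = FALSE])
  expect_equal(one$summary$mean, res$accuracy[1])
  expect_equal(one$summary$median, res$accuracy[1])
  # fig3: CV1 on the diagonal (cs label = vs cycle), CV2.1 off-diagonal with
  # direction preserved
  f3 <- sm$fig3_matrix
  expect_true(all(f3$cs_cycle_label[f3$scenario == "CV1"] ==
                    f3$vs_cycle[f3$scenario == "CV1"]))
  expect_true(all(f3$direction[f3$scenario == "CV2.1"] %in%
                    c("forward", "backward")))
  # means over replicates agree between summary and by_replicate
  s1 <- sm$summary[sm$summary$scenario == "CV1", ]
  br <- sm$by_replicate[sm$by_replicate$scenario == "CV1", ]
  expect_equal(s1$mean, mean(br$mean), tolerance = 1e-12)
})
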