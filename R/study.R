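#' Two-stage analysis of all cycles and traits of a plot-record set
#'
#' Runs the stage-1 lattice analysis per trial ([stage1_all_trials()]) and,
#' per cycle and trait, the weighted stage-2 fixed-genotype fit
#' ([stage2_blues()]) and the genotype-random variance-component fit
#' ([stage2_varcomp()]).
#'
#' @param plots plot records (see [simulate_testcross_trials()]).
#' @param traits traits to analyze (default: all present).
#' @param outlier_alpha Grubbs level for stage 1 (`NULL` disables).
#' @return List: `stage1` (adjusted means), `blues` (stage-2 BLUEs over all
#'   cycles x traits), `varcomp` (data.frame `cycle`, `trait`, `var_g`,
#'   `var_lt`, `var_gxlt`, `mean_vd`, `h2`).
#' @export
two_stage_pipeline <- function(plots, traits = unique(plots$trait),
                               outlier_alpha = 0.05) {
  s1 <- stage1_all_trials(plots, traits = traits,
                          outlier_alpha = outlier_alpha)
  s1$cycle <- plots$cycle[match(s1$line_id, plots$line_id)]
  blues <- list(); vc <- list()
  for (cy in sort(unique(s1$cycle))) {
    for (tr in traits) {
      m <- s1[s1$cycle == cy & s1$trait == tr, , drop = FALSE]
      if (!nrow(m)) next
      fit <- stage2_blues(m, tr)
      v <- stage2_varcomp(m, tr)
      blues[[length(blues) + 1L]] <- fit$blues
      vc[[length(vc) + 1L]] <- data.frame(
        cycle = cy, trait = tr, var_g = v$var_g, var_lt = v$var_lt,
        var_gxlt = v$var_gxlt, mean_vd = v$mean_vd, h2 = v$h2,
        stringsAsFactors = FALSE)
    }
  }
  list(stage1 = s1,
       blues = do.call(rbind, blues),
       varcomp = do.call(rbind, vc))
}

#' Simulate and analyze a complete breeding-program study
#'
#' End-to-end convenience wrapper: simulate the program, run the testcross
#' trials, corrupt/QC/impute the genotypes, build the expected (pedigree) and
#' realized (marker) kinship matrices, run the two-stage phenotype analysis,
#' and optionally the cross-validation study.
#'
#' @param config a [sim_config()].
#' @param traits traits to phenotype and analyze (default: all configured).
#' @param missing_rate genotype missingness before QC.
#' @param cv_scenarios scenarios for [run_cv()]; `NULL` skips CV.
#' @param cv_reps,cv_folds fold-plan dimensions.
#' @param cv_n_cs optional calibration-size override (see [run_cv()]).
#' @param models kernels to fit (`"GBLUP"`, `"PBLUP"`).
#' @return List with `sim`, `plots`, `geno_qc` (imputed post-QC genotypes),
#'   `qc_report`, `A`, `K`, `U`, `two_stage` and (when requested) `cv` and
#'   `cv_summary`.
#' @export
run_breeding_study <- function(config,
                               traits = sim_traits(config),
                               missing_rate = 0.02,
                               cv_scenarios = c("CV1", "CV2.1", "CV3"),
                               cv_reps = 10, cv_folds = 5,
                               cv_n_cs = NULL,
                               models = c("GBLUP", "PBLUP")) {
  sim <- simulate_breeding_program(config)
  arch <- make_trait_architecture(config, sim$genotypes)
  plots <- simulate_testcross_trials(config, sim, arch, traits = traits)

  G_raw <- corrupt_genotypes(sim$genotypes, missing_rate,
                             seed = derive_seed(config$seed, "corrupt"))
  qc <- filter_snps(G_raw)
  G <- impute_marginal(qc$genotypes, seed = derive_seed(config$seed, "impute"))

  A <- build_A(sim$pedigree)
  K <- expected_kinship(A)
  U <- realized_kinship(G)

  ts <- two_stage_pipeline(plots, traits = traits)

  out <- list(config = config, sim = sim, architecture = arch, plots = plots,
              geno_qc = G, qc_report = qc$report, A = A, K = K, U = U,
              two_stage = ts)
  if (!is.null(cv_scenarios)) {
    plan <- make_folds(sim$cycle_assignment, n_reps = cv_reps,
                       n_folds = cv_folds,
                       seed = derive_seed(config$seed, "folds"))
    kernels <- list()
    lines <- names(sim$cycle_assignment)
    if ("GBLUP" %in% models) kernels$GBLUP <- U[lines, lines]
    if ("PBLUP" %in% models) kernels$PBLUP <- K[lines, lines]
    out$cv <- run_cv(ts$blues, kernels, ts$varcomp[, c("cycle", "trait", "h2")],
                     plan, scenarios = cv_scenarios, n_cs = cv_n_cs,
                     u_matrix = U[lines, lines], traits = traits)
    out$cv_summary <- summarize_cv(out$cv)
    out$plan <- plan
  }
  out
}
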