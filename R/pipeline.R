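#' Read and cross-validate the pipeline's input files
#'
#' Loads genotypes (TSV or VCF), pedigree, genetic map and plot-level
#' phenotypes, and enforces id cross-referencing: every phenotyped line must
#' have genotype and pedigree rows. Mismatches are reported (first 20).
#'
#' @param paths named list/vector with elements `genotypes` (TSV path or VCF
#'   path ending in `.vcf`), `pedigree`, `map` (optional), `plots`.
#' @return Bundle list: `genotypes`, `pedigree`, `plots`.
#' @export
read_inputs <- function(paths) {
  need <- c("genotypes", "pedigree", "plots")
  missing_keys <- setdiff(need, names(paths))
  if (length(missing_keys))
    stop("missing input path(s): ", paste(missing_keys, collapse = ", "))
  for (k in intersect(c(need, "map"), names(paths)))
    if (!file.exists(paths[[k]]))
      stop("input file does not exist: ", paths[[k]])
  map <- if ("map" %in% names(paths)) read_map_csv(paths[["map"]]) else NULL
  G <- if (grepl("\\.vcf$", paths[["genotypes"]]))
    read_vcf_genotypes(paths[["genotypes"]], map)
  else read_genotypes_tsv(paths[["genotypes"]], map)
  ped <- read_pedigree_csv(paths[["pedigree"]])
  plots <- read_plots_csv(paths[["plots"]])
  pheno_lines <- unique(plots$line_id)
  no_geno <- setdiff(pheno_lines, rownames(G$dosage))
  no_ped <- setdiff(pheno_lines, ped$id)
  if (length(no_geno) || length(no_ped))
    stop("id cross-reference failure.",
         if (length(no_geno)) paste0(" No genotype for: ",
           paste(utils::head(no_geno, 20), collapse = ", "), "."),
         if (length(no_ped)) paste0(" No pedigree for: ",
           paste(utils::head(no_ped, 20), collapse = ", "), "."))
  list(genotypes = G, pedigree = ped, plots = plots)
}

pipeline_stages <- c("simulate", "qc", "twostage", "kinship", "cv")

#' Run the full pipeline: simulate/read, QC, two-stage, kinship, CV
#'
#' Executes the five stages in dependency order, writing each stage's outputs
#' under `out_dir` and a run manifest (`manifest.json`) with the config hash,
#' seeds, package version, per-stage output checksums and wall-clock times.
#' Re-running with an identical config reproduces identical checksums. On
#' stage failure the manifest records the failure point and partial outputs
#' are retained.
#'
#' @param config pipeline configuration: a list (or YAML file path) with
#'   elements `sim` (arguments for [sim_config()]) *or* `paths` (input files
#'   for [read_inputs()]), and optional blocks `qc` (`maf_min`,
#'   `max_missing`, `missing_rate`), `twostage` (`outlier_alpha`, `traits`)
#'   and `cv` (`scenarios`, `n_cs`, `models`, `n_reps`, `n_folds`; set
#'   `cv: ~` to skip).
#' @param out_dir output directory (created if needed).
#' @param stop_after optional stage name; the pipeline halts after it.
#' @return The run manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config, out_dir, stop_after = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(stop_after) && !stop_after %in% pipeline_stages)
    stop("unknown stage: ", stop_after)
  if (is.null(config$sim) && is.null(config$paths))
    stop("config error: need either a `sim` block or input `paths`")
  if (is.null(config$sim)) {
    for (p in unlist(config$paths))
      if (!file.exists(p)) stop("config error: input file missing: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("ryegp")),
                   stages = list())
  state <- new.env()
  checksum <- function(files) as.list(tools::md5sum(files))
  # every tabular output declares its column schema in a sidecar
  schemas <- list()
  note_schema <- function(files) {
    for (f in files) {
      if (grepl("\\.csv$", f))
        schemas[[basename(f)]] <<- names(utils::read.csv(f, nrows = 1))
      else if (grepl("\\.tsv$", f))
        schemas[[basename(f)]] <<- names(utils::read.delim(f, nrows = 1,
                                                           check.names = FALSE))
    }
  }

  stage_fns <- list(
    simulate = function() {
      if (!is.null(config$sim)) {
        cfg <- do.call(sim_config, config$sim)
        state$config <- cfg
        state$sim <- simulate_breeding_program(cfg)
        arch <- make_trait_architecture(cfg, state$sim$genotypes)
        state$plots <- simulate_testcross_trials(cfg, state$sim, arch)
        qcb <- config$qc
        mr <- if (is.null(qcb$missing_rate)) 0.02 else qcb$missing_rate
        state$G_raw <- corrupt_genotypes(state$sim$genotypes, mr,
                                         seed = derive_seed(cfg$seed, "corrupt"))
        state$seed <- cfg$seed
        fp <- file.path(out_dir, c("pedigree.csv", "genotypes.tsv", "map.csv",
                                   "plots.csv"))
        write_pedigree_csv(state$sim$pedigree, fp[1])
        write_genotypes_tsv(state$G_raw, fp[2])
        write_map_csv(state$sim$genotypes$map, fp[3])
        write_plots_csv(state$plots, fp[4])
        state$pedigree <- state$sim$pedigree
        fp
      } else {
        bundle <- read_inputs(config$paths)
        state$G_raw <- bundle$genotypes
        state$pedigree <- bundle$pedigree
        state$plots <- bundle$plots
        state$seed <- if (is.null(config$seed)) 1L else config$seed
        character(0)
      }
    },
    qc = function() {
      qcb <- config$qc
      qc <- filter_snps(state$G_raw,
                        maf_min = if (is.null(qcb$maf_min)) 0.01 else qcb$maf_min,
                        max_missing = if (is.null(qcb$max_missing)) 0.10
                                      else qcb$max_missing)
      state$G <- impute_marginal(qc$genotypes,
                                 seed = derive_seed(state$seed, "impute"))
      fp <- file.path(out_dir, c("genotypes_qc.tsv", "qc_report.csv"))
      write_genotypes_tsv(state$G, fp[1])
      utils::write.csv(data.frame(
        n_input = qc$report$n_input, n_passed = qc$report$n_passed,
        removed_missingness = qc$report$removed[["missingness"]],
        removed_maf = qc$report$removed[["maf"]]), fp[2], row.names = FALSE)
      fp
    },
    twostage = function() {
      tb <- config$twostage
      traits <- if (is.null(tb$traits)) unique(state$plots$trait) else tb$traits
      alpha <- if (is.null(tb$outlier_alpha)) 0.05 else tb$outlier_alpha
      state$ts <- two_stage_pipeline(state$plots, traits = traits,
                                     outlier_alpha = alpha)
      fp <- file.path(out_dir, c("adjusted_means.csv", "blues.csv",
                                 "varcomp.csv"))
      utils::write.csv(state$ts$stage1, fp[1], row.names = FALSE)
      utils::write.csv(state$ts$blues, fp[2], row.names = FALSE)
      utils::write.csv(state$ts$varcomp, fp[3], row.names = FALSE)
      fp
    },
    kinship = function() {
      state$A <- build_A(state$pedigree)
      state$K <- expected_kinship(state$A)
      state$U <- realized_kinship(state$G)
      fp <- file.path(out_dir, c("kinship_K.tsv", "kinship_U.tsv"))
      write_kinship_tsv(state$K, fp[1])
      write_kinship_tsv(state$U, fp[2])
      fp
    },
    cv = function() {
      cvb <- config$cv
      if (is.null(cvb) && !is.null(config$sim)) cvb <- list()
      if (is.null(cvb)) return(character(0))
      lines <- unique(state$ts$blues$line_id)
      ca <- stats::setNames(
        state$ts$blues$cycle[match(lines, state$ts$blues$line_id)], lines)
      plan <- make_folds(ca,
                         n_reps = if (is.null(cvb$n_reps)) 10 else cvb$n_reps,
                         n_folds = if (is.null(cvb$n_folds)) 5 else cvb$n_folds,
                         seed = derive_seed(state$seed, "folds"))
      models <- if (is.null(cvb$models)) c("GBLUP", "PBLUP") else cvb$models
      kernels <- list()
      if ("GBLUP" %in% models) kernels$GBLUP <- state$U[lines, lines]
      if ("PBLUP" %in% models) kernels$PBLUP <- state$K[lines, lines]
      scen <- if (is.null(cvb$scenarios)) c("CV1", "CV2.1", "CV3")
              else cvb$scenarios
      res <- run_cv(state$ts$blues, kernels,
                    state$ts$varcomp[, c("cycle", "trait", "h2")],
                    plan, scenarios = scen, n_cs = cvb$n_cs,
                    u_matrix = state$U[lines, lines])
      sm <- summarize_cv(res)
      fp <- file.path(out_dir, c("cv_results.csv", "cv_summary.csv"))
      utils::write.csv(res, fp[1], row.names = FALSE)
      utils::write.csv(sm$summary, fp[2], row.names = FALSE)
      fp
    })

  for (st in pipeline_stages) {
    t0 <- proc.time()[["elapsed"]]
    outfiles <- tryCatch(stage_fns[[st]](), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(outfiles, "error")) {
      manifest$stages[[st]] <- list(status = "failed",
                                    error = conditionMessage(outfiles),
                                    elapsed_s = elapsed)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline failed at stage `", st, "`: ",
           conditionMessage(outfiles))
    }
    manifest$stages[[st]] <- list(status = "ok",
                                  outputs = checksum(outfiles),
                                  elapsed_s = round(elapsed, 3))
    note_schema(outfiles)
    if (!is.null(stop_after) && st == stop_after) break
  }
  jsonlite::write_json(schemas, file.path(out_dir, "schemas.json"),
                       pretty = TRUE)
  manifest$seed <- state$seed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
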