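#' Build the replicated fold plan shared by all CV scenarios
#'
#' Ten-times replicated fivefold cross-validation (by default) with random
#' sampling within each cycle: per replicate, each cycle's lines are
#' partitioned into `n_folds` validation folds of (near-)equal size. The same
#' allocation of lines to validation folds is reused by every scenario and
#' model so that accuracies are directly comparable.
#'
#' @param cycle_assignment named vector line_id -> cycle.
#' @param n_reps number of replicates.
#' @param n_folds folds per replicate.
#' @param seed integer seed.
#' @return data.frame `line_id`, `cycle`, `replicate`, `fold` with attributes
#'   `seed`, `n_reps`, `n_folds`.
#' @export
make_folds <- function(cycle_assignment, n_reps = 10, n_folds = 5, seed = 1L) {
  cycles <- sort(unique(cycle_assignment))
  for (cy in cycles)
    if (sum(cycle_assignment == cy) < n_folds)
      stop("cycle ", cy, " has fewer lines than folds")
  uneven <- cycles[vapply(cycles, function(cy)
    sum(cycle_assignment == cy) %% n_folds != 0, logical(1))]
  if (length(uneven))
    message("fold sizes differ by <= 1 in cycle(s): ",
            paste(uneven, collapse = ", "))
  plan <- with_stream(seed, "folds", {
    rows <- list()
    for (r in seq_len(n_reps)) {
      for (cy in cycles) {
        ids <- names(cycle_assignment)[cycle_assignment == cy]
        n <- length(ids)
        rows[[length(rows) + 1L]] <- data.frame(
          line_id = sample(ids), cycle = cy, replicate = r,
          fold = rep(seq_len(n_folds), length.out = n),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  rownames(plan) <- NULL
  attr(plan, "seed") <- seed
  attr(plan, "n_reps") <- n_reps
  attr(plan, "n_folds") <- n_folds
  plan
}

#' Calibration-set construction for a CV scenario
#'
#' Given the shared fold plan, one replicate and one validation fold of the
#' validation cycle, assembles the calibration set:
#' * `CV1` — the validation cycle's remaining folds;
#' * `CV2.x` — `n_cs / x` lines sampled without replacement from each of the
#'   `x` calibration cycles (the validation cycle contributes nothing);
#' * `CV3` — equal samples from all cycles, with the validation fold excluded
#'   from its own cycle's pool.
#' Multi-cycle calibration sets always draw the same number of lines from
#' each contributing cycle. Sampling is reproducible from the plan's root
#' seed.
#'
#' @param scenario list with `name` (`"CV1"`, `"CV2.1"`, `"CV2.2"`, `"CV2.3"`
#'   or `"CV3"`), `vs_cycle`, `cs_cycles`, and `n_cs` (ignored for CV1).
#' @param plan a [make_folds()] result.
#' @param replicate,fold indices into the plan.
#' @return Character vector of calibration line ids.
#' @export
build_cs <- function(scenario, plan, replicate, fold) {
  name <- scenario$name
  vs_cycle <- scenario$vs_cycle
  cs_cycles <- scenario$cs_cycles
  prep <- plan[plan$replicate == replicate, , drop = FALSE]
  vs_ids <- prep$line_id[prep$cycle == vs_cycle & prep$fold == fold]
  if (!length(vs_ids)) stop("empty validation fold")
  if (name == "CV1")
    return(prep$line_id[prep$cycle == vs_cycle & prep$fold != fold])
  if (grepl("^CV2", name) && vs_cycle %in% cs_cycles)
    stop("CV2 calibration cycles must exclude the validation cycle")
  n_cs <- scenario$n_cs
  k <- length(cs_cycles)
  # equal per-cycle quotas; when n_cs is not divisible by k (e.g. 208 lines
  # from three cycles) counts differ by at most one
  quotas <- rep(n_cs %/% k, k) + (seq_len(k) <= n_cs %% k)
  key <- paste("cs", name, vs_cycle, paste(cs_cycles, collapse = "+"),
               n_cs, replicate, fold, sep = "/")
  with_stream(attr(plan, "seed"), key, {
    cs <- character(0)
    for (i in seq_along(cs_cycles)) {
      cy <- cs_cycles[i]
      quota <- quotas[i]
      pool <- if (cy == vs_cycle)
        prep$line_id[prep$cycle == cy & prep$fold != fold]
      else prep$line_id[prep$cycle == cy]
      if (quota > length(pool))
        stop("requested ", quota, " lines from cycle ", cy, " but only ",
             length(pool), " available")
      cs <- c(cs, if (quota == length(pool)) pool else sample(pool, quota))
    }
    cs
  })
}

#' Heritability-corrected prediction accuracy
#'
#' `accuracy = rho / sqrt(h2_v)` with `rho` the predictive ability (Pearson
#' correlation of predicted and observed testcross values) and `h2_v` the
#' progeny-mean heritability of the validation cycle and trait. Values above
#' 1 can occur by sampling noise and are not clipped; values above 1.1 are
#' flagged with a warning.
#'
#' @param rho predictive ability.
#' @param h2_v validation-set heritability in (0, 1].
#' @export
accuracy <- function(rho, h2_v) {
  if (!is.finite(h2_v) || h2_v <= 0) stop("h2_v must be in (0, 1]")
  if (h2_v > 1) stop("h2_v must be in (0, 1]")
  acc <- rho / sqrt(h2_v)
  if (is.finite(acc) && abs(acc) > 1.1)
    warning("accuracy ", signif(acc, 3), " exceeds 1.1")
  acc
}

# Enumerate (vs_cycle, cs_cycles, n_cs) combinations for one scenario name.
scenario_grid <- function(name, cycles, n_cs_unit, n_cs = NULL) {
  combos <- list()
  add <- function(vs, cs, n) combos[[length(combos) + 1L]] <<- list(
    name = name, vs_cycle = vs, cs_cycles = cs, n_cs = n)
  for (vs in cycles) {
    others <- setdiff(cycles, vs)
    if (name == "CV1") add(vs, vs, n_cs_unit)
    else if (name == "CV2.1") {
      sizes <- if (is.null(n_cs)) n_cs_unit else n_cs
      for (cs in others) for (n in sizes) add(vs, cs, n)
    } else if (name == "CV2.2") {
      sizes <- if (is.null(n_cs)) n_cs_unit else n_cs
      prs <- utils::combn(others, 2, simplify = FALSE)
      for (cs in prs) for (n in sizes) add(vs, cs, n)
    } else if (name == "CV2.3") {
      sizes <- if (is.null(n_cs)) n_cs_unit * (1:3) else n_cs
      for (n in sizes) add(vs, others, n)
    } else if (name == "CV3") {
      sizes <- if (is.null(n_cs)) n_cs_unit * seq_along(cycles) else n_cs
      for (n in sizes) add(vs, cycles, n)
    } else stop("unknown scenario: ", name)
  }
  combos
}

#' Run the cross-validation study
#'
#' For every requested scenario, model, trait, replicate and fold: build the
#' calibration set with [build_cs()], fit the kernel model with [reml_fit()]
#' on the calibration BLUEs, predict the validation lines, and record the
#' predictive ability `rho` (Pearson correlation of predicted and observed
#' BLUEs), the heritability-corrected [accuracy()], and the mean maximum
#' realized kinship of the calibration/validation pair. Across-cycle
#' scenarios include both forward (calibration cycles precede the validation
#' cycle) and backward directions; mixed-direction combinations are labelled
#' `"mixed"`.
#'
#' @param blues data.frame `line_id`, `cycle`, `trait`, `blue` covering all
#'   lines.
#' @param kernels named list of kinship matrices, one per model (e.g.
#'   `list(GBLUP = U, PBLUP = K)`).
#' @param h2 data.frame `cycle`, `trait`, `h2` (validation-cycle
#'   heritabilities).
#' @param plan a [make_folds()] result.
#' @param scenarios character vector of scenario names.
#' @param n_cs optional named list overriding the calibration-set sizes per
#'   scenario name (defaults: one fold-complement unit for CV1/CV2.1/CV2.2,
#'   units x 1:3 for CV2.3, units x 1:4 for CV3).
#' @param u_matrix realized kinship used for the relatedness diagnostic
#'   (default: the `GBLUP` kernel if present).
#' @param traits subset of traits (default: all in `blues`).
#' @return `cv_result` data.frame: one row per scenario x model x trait x
#'   combination x replicate x fold with `rho`, `accuracy`, `u_max_mean`,
#'   `note`.
#' @export
run_cv <- function(blues, kernels, h2, plan,
                   scenarios = c("CV1", "CV2.1", "CV2.3", "CV3"),
                   n_cs = NULL, u_matrix = kernels[["GBLUP"]],
                   traits = unique(blues$trait)) {
  cycles <- sort(unique(plan$cycle))
  n_folds <- attr(plan, "n_folds")
  n_reps <- attr(plan, "n_reps")
  cyc_size <- sum(plan$cycle == cycles[1] & plan$replicate == 1)
  n_cs_unit <- round(cyc_size * (n_folds - 1) / n_folds)
  for (tr in traits)
    for (cy in cycles)
      if (!any(h2$cycle == cy & h2$trait == tr))
        stop("missing heritability for cycle ", cy, " trait ", tr)
  rows <- list()
  for (sc_name in scenarios) {
    combos <- scenario_grid(sc_name, cycles, n_cs_unit, n_cs[[sc_name]])
    for (combo in combos) {
      dir <- if (sc_name %in% c("CV1", "CV3")) sc_name
      else if (all(combo$cs_cycles < combo$vs_cycle)) "forward"
      else if (all(combo$cs_cycles > combo$vs_cycle)) "backward"
      else "mixed"
      for (r in seq_len(n_reps)) for (f in seq_len(n_folds)) {
        cs <- build_cs(combo, plan, r, f)
        prep <- plan[plan$replicate == r, ]
        vs <- prep$line_id[prep$cycle == combo$vs_cycle & prep$fold == f]
        umm <- if (is.null(u_matrix)) NA_real_
          else mean_max_kinship(u_matrix, cs, vs)$u_max_mean
        for (model in names(kernels)) {
          Kcs <- kernels[[model]][cs, cs]
          eg <- eigen((Kcs + t(Kcs)) / 2, symmetric = TRUE)
          for (tr in traits) {
            btr <- blues[blues$trait == tr, c("line_id", "cycle", "blue")]
            fit <- reml_fit(btr, kernels[[model]], cs,
                            all_ids = union(cs, vs), eigen_cs = eg)
            prd <- predict_testcross(fit, vs)
            obs <- btr$blue[match(vs, btr$line_id)]
            note <- ""
            if (stats::sd(prd$predicted) < 1e-12 || stats::sd(obs) < 1e-12) {
              rho <- NA_real_; acc <- NA_real_
              note <- "degenerate: constant predictions or observations"
            } else {
              rho <- stats::cor(prd$predicted, obs)
              h2v <- h2$h2[h2$cycle == combo$vs_cycle & h2$trait == tr][1]
              acc <- suppressWarnings(accuracy(rho, h2v))
            }
            rows[[length(rows) + 1L]] <- data.frame(
              scenario = sc_name, model = model, trait = tr,
              replicate = r, fold = f, vs_cycle = combo$vs_cycle,
              cs_cycles = paste(combo$cs_cycles, collapse = "+"),
              direction = dir, n_cs = length(cs), rho = rho,
              accuracy = acc, u_max_mean = umm, note = note,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("cv_result", class(res))
  res
}

#' Paired model comparison after Fisher's Z transformation
#'
#' Pairs two cross-validation result sets on (scenario, trait, combination,
#' replicate, fold), applies Fisher's Z (`atanh`) to the predictive abilities
#' `rho` — which are bounded in [-1, 1], unlike the heritability-corrected
#' accuracies — and reports a paired two-sided t-test per scenario x trait.
#'
#' @param a,b `cv_result` data.frames with identical keys (e.g. GBLUP vs
#'   PBLUP runs).
#' @return data.frame per scenario x trait: `n_pairs`, `mean_rho_a`,
#'   `mean_rho_b`, `mean_z_diff`, `t`, `df`, `p`.
#' @export
compare_models <- function(a, b) {
  keys <- c("scenario", "trait", "replicate", "fold", "vs_cycle",
            "cs_cycles", "n_cs")
  ka <- do.call(paste, c(a[keys], sep = "|"))
  kb <- do.call(paste, c(b[keys], sep = "|"))
  if (length(ka) != length(kb) || !setequal(ka, kb) || anyDuplicated(ka))
    stop("result sets do not share identical (scenario, replicate, fold) keys")
  b <- b[match(ka, kb), ]
  z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  out <- list()
  for (grp in split(seq_len(nrow(a)),
                    list(a$scenario, a$trait), drop = TRUE)) {
    za <- z(a$rho[grp]); zb <- z(b$rho[grp])
    ok <- is.finite(za) & is.finite(zb)
    dif <- za[ok] - zb[ok]
    n <- length(dif)
    if (n < 2 || stats::sd(dif) < 1e-14) {
      tt <- list(statistic = 0, parameter = n - 1, p.value = 1)
    } else tt <- stats::t.test(dif)
    out[[length(out) + 1L]] <- data.frame(
      scenario = a$scenario[grp[1]], trait = a$trait[grp[1]],
      n_pairs = n,
      mean_rho_a = mean(a$rho[grp], na.rm = TRUE),
      mean_rho_b = mean(b$rho[grp], na.rm = TRUE),
      mean_z_diff = mean(dif),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary tables of a cross-validation study
#'
#' @param results a [run_cv()] result.
#' @return List of data.frames:
#'   `summary` (mean/median/quartiles of accuracy per scenario x model x
#'   trait x n_cs), `by_replicate` (mean accuracy per replicate, the unit of
#'   the directional sign checks), `fig3_matrix` (within-cycle CV1 diagonal
#'   and across-cycle CV2.1 off-diagonal mean accuracies per calibration x
#'   validation cycle, forward/backward preserved), `fig4_pairs` (mean
#'   accuracy vs mean maximum kinship per CV2.1 directed pair, with the
#'   Pearson correlation per model x trait) and `fig5_boxdata` (fold-level
#'   CV2.3/CV3 accuracies for box plots).
#' @export
summarize_cv <- function(results) {
  agg <- function(d, by) {
    sp <- split(seq_len(nrow(d)), d[by], drop = TRUE)
    out <- lapply(sp, function(i) {
      x <- d$accuracy[i]
      cbind(d[i[1], by, drop = FALSE],
            data.frame(n = sum(is.finite(x)),
                       mean = mean(x, na.rm = TRUE),
                       median = stats::median(x, na.rm = TRUE),
                       q1 = unname(stats::quantile(x, 0.25, na.rm = TRUE)),
                       q3 = unname(stats::quantile(x, 0.75, na.rm = TRUE)),
                       mean_rho = mean(d$rho[i], na.rm = TRUE),
                       mean_u_max = mean(d$u_max_mean[i], na.rm = TRUE)))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
  summary <- agg(results, c("scenario", "model", "trait", "n_cs"))
  by_replicate <- agg(results,
                      c("scenario", "model", "trait", "n_cs", "replicate"))
  m12 <- results[results$scenario %in% c("CV1", "CV2.1"), ]
  fig3 <- NULL
  if (nrow(m12)) {
    m12$cs_cycle_label <- ifelse(m12$scenario == "CV1",
                                 as.character(m12$vs_cycle), m12$cs_cycles)
    fig3 <- agg(m12, c("model", "trait", "scenario", "cs_cycle_label",
                       "vs_cycle", "direction"))
  }
  c21 <- results[results$scenario == "CV2.1", ]
  fig4 <- NULL
  if (nrow(c21)) {
    fig4 <- agg(c21, c("model", "trait", "cs_cycles", "vs_cycle", "direction"))
    cors <- lapply(split(seq_len(nrow(fig4)),
                         fig4[c("model", "trait")], drop = TRUE),
                   function(i) cbind(fig4[i[1], c("model", "trait")],
                                     data.frame(pearson_r = if (length(i) > 2)
                                       stats::cor(fig4$mean_u_max[i],
                                                  fig4$mean[i]) else NA_real_)))
    attr(fig4, "accuracy_vs_umax") <- do.call(rbind, cors)
  }
  fig5 <- results[results$scenario %in% c("CV2.3", "CV3"), ]
  list(summary = summary, by_replicate = by_replicate,
       fig3_matrix = fig3, fig4_pairs = fig4, fig5_boxdata = fig5)
}
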