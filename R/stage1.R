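#' Grubbs critical value
#'
#' Critical value of the maximum absolute studentized deviate for a sample of
#' size `n` at two-sided level `alpha`, from the t-distribution:
#' `G = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative Grubbs outlier detection
#'
#' One-at-a-time maximum-deviate test: compute
#' `G = max_i |r_i - rbar| / s`, compare against [grubbs_critical()], remove
#' the offending observation, recompute and repeat until no rejection.
#'
#' @param residuals numeric vector.
#' @param alpha significance level per step (default 0.05).
#' @return Integer indices into `residuals` of removed values, in removal
#'   order (empty when nothing is rejected; `n < 3` yields an empty result
#'   with a warning).
#' @export
detect_outliers_grubbs <- function(residuals, alpha = 0.05) {
  n <- length(residuals)
  if (n < 3) {
    warning("fewer than 3 residuals; Grubbs test not applicable")
    return(integer(0))
  }
  idx <- seq_len(n)
  removed <- integer(0)
  r <- residuals
  while (length(r) >= 3) {
    s <- stats::sd(r)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) break
    dev <- abs(r - mean(r)) / s
    i <- which.max(dev)
    if (dev[i] > grubbs_critical(length(r), alpha)) {
      removed <- c(removed, idx[i])
      r <- r[-i]
      idx <- idx[-i]
    } else break
  }
  removed
}

#' Stage-1 adjusted entry means for one trial (location.tester x trait)
#'
#' Lattice analysis of the plot records of a single location.tester: linear
#' mixed model with genotype and replicate fixed and incomplete block within
#' replicate random; the adjusted mean of a genotype is its generalized-least-
#' squares estimate at the average replicate level, with its standard error
#' from the fixed-effect covariance matrix. Single-replicate traits reduce to
#' block-adjusted means (genotype fixed, block random). Outliers are removed
#' iteratively from the plot-level residuals by [detect_outliers_grubbs()]
#' (refitting after each sweep).
#'
#' @param plots plot records (see [simulate_testcross_trials()]).
#' @param location,tester,trait selectors for the trial.
#' @param outlier_alpha Grubbs level; `NULL` disables outlier removal.
#' @return data.frame `line_id`, `cycle`, `location`, `tester`, `loc_tester`,
#'   `trait`, `blue`, `se`, `n_plots`, with attribute `n_outliers_removed`.
#' @export
stage1_adjusted_means <- function(plots, location, tester, trait,
                                  outlier_alpha = 0.05) {
  d <- plots[plots$location == location & plots$tester == tester &
               plots$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no plot records for ", location, ".", tester,
                         " / ", trait)
  if (anyDuplicated(d[, c("line_id", "replicate", "block")]))
    stop("duplicate plot rows in ", location, ".", tester)
  if (anyDuplicated(d[, c("line_id", "replicate")]))
    stop("line observed twice within a replicate in ", location, ".", tester)
  n_out_total <- 0L
  for (sweep in 1:10) {
    fit <- fit_lattice(d)
    if (is.null(outlier_alpha)) break
    res <- stats::residuals(fit)
    out <- suppressWarnings(detect_outliers_grubbs(res, outlier_alpha))
    if (!length(out)) break
    d <- d[-out, , drop = FALSE]
    n_out_total <- n_out_total + length(out)
  }
  am <- adjusted_means_from_fit(fit, d)
  res <- data.frame(line_id = am$line_id,
                    cycle = d$cycle[match(am$line_id, d$line_id)],
                    location = location, tester = tester,
                    loc_tester = paste(location, tester, sep = "."),
                    trait = trait, blue = am$blue, se = am$se,
                    n_plots = as.integer(table(d$line_id)[am$line_id]),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_outliers_removed") <- n_out_total
  res
}

# Fit the lattice model for one trial's plot data. With a single replicate
# the genotype-fixed model is saturated (one plot per line), so block
# adjustment uses an intercept + random-block model instead; the entry mean
# is then the plot value minus the block BLUP.
fit_lattice <- function(d) {
  d$line_id <- factor(d$line_id)
  d$replicate <- factor(d$replicate)
  d$blk <- factor(paste(d$replicate, d$block, sep = ":"))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fml <- if (nlevels(d$replicate) > 1)
    value ~ 0 + line_id + replicate + (1 | blk)
  else
    value ~ 1 + (1 | blk)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, control = ctrl),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("singular|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (any(is.na(lme4::fixef(fit))))
    stop("unestimable genotype means (disconnected blocks) in trial: ",
         "fixed-effect rank deficiency")
  fit
}

# Adjusted means at the average replicate level, with GLS standard errors.
# Single-replicate trials: plot value minus the block BLUP, with the
# residual standard deviation (which includes the genetic variance, common
# to all entries of the trial) as the per-entry standard error.
adjusted_means_from_fit <- function(fit, d) {
  beta <- lme4::fixef(fit)
  if (length(beta) == 1 && names(beta)[1] == "(Intercept)" &&
      !any(grepl("^line_id", names(beta)))) {
    blk <- factor(paste(d$replicate, d$block, sep = ":"))
    re <- lme4::ranef(fit)$blk
    blup <- stats::setNames(re[["(Intercept)"]], rownames(re))
    adj <- d$value - blup[as.character(blk)]
    return(data.frame(line_id = d$line_id, blue = unname(adj),
                      se = stats::sigma(fit), stringsAsFactors = FALSE))
  }
  V <- as.matrix(stats::vcov(fit))
  g_names <- grep("^line_id", names(beta), value = TRUE)
  r_names <- grep("^replicate", names(beta), value = TRUE)
  lines <- sub("^line_id", "", g_names)
  p <- length(beta)
  R <- length(r_names) + 1L  # reference replicate included
  C <- matrix(0, length(g_names), p, dimnames = list(lines, names(beta)))
  C[cbind(seq_along(g_names), match(g_names, names(beta)))] <- 1
  if (length(r_names)) C[, r_names] <- 1 / R
  blue <- drop(C %*% beta)
  se <- sqrt(rowSums((C %*% V) * C))
  data.frame(line_id = lines, blue = blue, se = se, stringsAsFactors = FALSE)
}

#' Stage-1 means for every trial of a plot-record set
#'
#' Convenience wrapper running [stage1_adjusted_means()] over all
#' location.tester x trait combinations present.
#'
#' @inheritParams stage1_adjusted_means
#' @param traits subset of traits (default: all present).
#' @export
stage1_all_trials <- function(plots, traits = unique(plots$trait),
                              outlier_alpha = 0.05) {
  combos <- unique(plots[plots$trait %in% traits,
                         c("location", "tester", "trait")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    out[[i]] <- stage1_adjusted_means(plots, combos$location[i],
                                      combos$tester[i], combos$trait[i],
                                      outlier_alpha = outlier_alpha)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
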