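# Profile REML machinery for the stage-2 genotype-fixed weighted model.
#
# Model for one cycle x trait, observations = stage-1 adjusted means:
#   y = X beta + (location.tester) + (genotype x location.tester) + e*
# with V = sigma_e^2 * H,  H = rho_lt Z1 Z1' + rho_gxl I + diag(se^2),
# X the genotype incidence (one column per line). The location.tester blocks
# make H block-diagonal with a diagonal-plus-rank-one block per trial, so all
# solves use the Sherman-Morrison identity and cost O(n) per block.
stage2_profile <- function(y, g, lt, se2, rho_lt, rho_gxl) {
  g <- as.integer(g); lt_f <- as.integer(lt)
  ng <- max(g)
  acc_diag <- numeric(ng)      # X' E^-1 X (diagonal)
  Xy <- numeric(ng)            # X' H^-1 y accumulator
  M <- matrix(0, ng, ng)       # X' H^-1 X
  yHy <- 0
  logdetH <- 0
  for (l in seq_len(max(lt_f))) {
    rows <- which(lt_f == l)
    e <- rho_gxl + se2[rows]
    ei <- 1 / e
    s <- sum(ei)
    c_l <- rho_lt / (1 + rho_lt * s)
    gi <- g[rows]
    w <- numeric(ng); w[gi] <- ei           # X_l' E^-1 1
    # X_l' E_l^-1 X_l is diagonal with entries ei at gi
    acc_diag[gi] <- acc_diag[gi] + ei
    M <- M - c_l * tcrossprod(w)
    u <- sum(ei * y[rows])                  # 1' E^-1 y
    Xy[gi] <- Xy[gi] + ei * y[rows]
    Xy <- Xy - c_l * u * w
    yHy <- yHy + sum(ei * y[rows]^2) - c_l * u^2
    logdetH <- logdetH + sum(log(e)) + log1p(rho_lt * s)
  }
  diag(M) <- diag(M) + acc_diag
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), Xy))
  rss <- yHy - sum(beta * Xy)              # r' H^-1 r
  n <- length(y); p <- ng
  sigma2 <- max(rss / (n - p), .Machine$double.eps)
  logdetM <- 2 * sum(log(diag(ch)))
  m2ll <- (n - p) * log(sigma2) + logdetH + logdetM + (n - p)
  list(beta = beta, sigma2 = sigma2, m2ll = m2ll, chol_M = ch)
}

#' Stage-2 weighted analysis: across-trial BLUEs of testcross means
#'
#' Combines stage-1 adjusted means of one cycle and trait across
#' location.tester units with a weighted mixed model: genotype fixed,
#' location.tester and genotype x location.tester random, and residual
#' variances proportional to the squared stage-1 standard errors (the
#' diagonal approximation of the stage-1 precision, the standard weighting
#' for stage-wise analyses of trial series). Variance
#' ratios are estimated by profile REML with a derivative-free Nelder-Mead
#' search on the log scale (converged when successive objective values differ
#' by < 1e-8); the genotype BLUEs, their standard errors and the mean
#' variance of a difference of two BLUEs are computed at the REML estimates.
#'
#' With a single location.tester the interaction and trial variance are
#' inestimable; the fit is carried out with both fixed at zero and flagged
#' (`single_lt = TRUE`), reproducing the stage-1 means.
#'
#' @param means stage-1 adjusted means for one cycle (data.frame with
#'   `line_id`, `loc_tester`, `trait`, `blue`, `se`).
#' @param trait trait to analyze (default: the single trait present).
#' @return List of class `stage2_fit`: `blues` (data.frame `line_id`, `cycle`,
#'   `trait`, `blue`, `se`), `varcomp` (`sigma2_lt`, `sigma2_gxlt`,
#'   `sigma2_e_scale`), `mean_vd`, `single_lt`, `converged`.
#' @export
stage2_blues <- function(means, trait = NULL) {
  if (is.null(trait)) {
    trait <- unique(means$trait)
    if (length(trait) != 1) stop("multiple traits present; specify `trait`")
  }
  d <- means[means$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no adjusted means for trait ", trait)
  if (anyDuplicated(d[, c("line_id", "loc_tester")]))
    stop("duplicate line x location.tester rows")
  if (any(!is.finite(d$se) | d$se <= 0)) stop("standard errors must be > 0")
  g <- factor(d$line_id)
  lt <- factor(d$loc_tester)
  se2 <- d$se^2
  y <- d$blue
  single_lt <- nlevels(lt) < 2
  if (single_lt) {
    prof <- stage2_profile(y, g, lt, se2, 0, 0)
    rho <- c(0, 0)
    converged <- TRUE
  } else {
    obj <- function(lr) {
      pr <- stage2_profile(y, g, lt, se2, exp(lr[1]), exp(lr[2]))
      if (is.null(pr)) return(1e10)
      pr$m2ll
    }
    med_se2 <- stats::median(se2)
    opt <- stats::optim(log(c(med_se2, med_se2)), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 500))
    rho <- exp(opt$par)
    converged <- opt$convergence == 0
    prof <- stage2_profile(y, g, lt, se2, rho[1], rho[2])
    if (is.null(prof))
      stop("stage-2 REML failed: singular GLS system; iteration trace: ",
           paste(utils::head(signif(opt$par, 4)), collapse = ", "))
  }
  ng <- nlevels(g)
  Minv <- chol2inv(prof$chol_M)
  C <- prof$sigma2 * Minv
  s <- sum(diag(C)); S <- sum(C)
  mean_vd <- if (ng > 1) 2 * (ng * s - S) / (ng * (ng - 1)) else NA_real_
  cyc <- if ("cycle" %in% names(d)) d$cycle[match(levels(g), d$line_id)]
         else NA_integer_
  out <- list(
    blues = data.frame(line_id = levels(g), cycle = cyc, trait = trait,
                       blue = prof$beta, se = sqrt(diag(C)),
                       stringsAsFactors = FALSE),
    varcomp = c(sigma2_lt = rho[1] * prof$sigma2,
                sigma2_gxlt = rho[2] * prof$sigma2,
                sigma2_e_scale = prof$sigma2),
    mean_vd = mean_vd,
    single_lt = single_lt,
    converged = converged)
  class(out) <- "stage2_fit"
  out
}

#' Stage-2 variance components and progeny-mean heritability
#'
#' Same weighted model as [stage2_blues()] but with genotype random,
#' fitted by REML via [lme4::lmer()]; the genotypic variance from this fit is
#' combined with the mean variance of a difference of two genotype BLUEs from
#' the genotype-fixed fit to give the progeny-mean heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + vbar_delta / 2)`.
#'
#' @inheritParams stage2_blues
#' @return List of class `stage2_varcomp`: `var_g`, `var_lt`, `var_gxlt`,
#'   `var_resid_scale`, `mean_vd`, `h2`, `single_lt`.
#' @export
stage2_varcomp <- function(means, trait = NULL) {
  if (is.null(trait)) {
    trait <- unique(means$trait)
    if (length(trait) != 1) stop("multiple traits present; specify `trait`")
  }
  fixed_fit <- stage2_blues(means, trait)
  d <- means[means$trait == trait, , drop = FALSE]
  d$g <- factor(d$line_id)
  d$lt <- factor(d$loc_tester)
  d$glt <- interaction(d$g, d$lt, drop = TRUE)
  d$w <- 1 / d$se^2
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fml <- if (fixed_fit$single_lt) blue ~ 1 + (1 | g)
         else blue ~ 1 + (1 | g) + (1 | lt) + (1 | glt)
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(fml, data = d, weights = w, control = ctrl),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) {
        if (grepl("singular|converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) stop("stage-2 variance-component REML failed: ",
                             conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  var_g <- getv("g")
  out <- list(var_g = var_g,
              var_lt = getv("lt"),
              var_gxlt = getv("glt"),
              var_resid_scale = getv("Residual"),
              mean_vd = fixed_fit$mean_vd,
              h2 = heritability(var_g, fixed_fit$mean_vd),
              single_lt = fixed_fit$single_lt)
  class(out) <- "stage2_varcomp"
  out
}

#' Progeny-mean heritability
#'
#' `h2 = sigma_g^2 / (sigma_g^2 + vbar_delta / 2)` with `vbar_delta` the mean
#' variance of a difference of two genotype BLUEs — the precision-based
#' generalization of the classical line-mean heritability to unbalanced
#' multi-environment trials.
#'
#' @param var_g genotypic variance (>= 0).
#' @param mean_vd mean variance of a difference of two BLUEs (> 0).
#' @export
heritability <- function(var_g, mean_vd) {
  stopifnot(var_g >= 0)
  if (!is.finite(mean_vd) || mean_vd <= 0)
    stop("mean variance of a difference must be positive")
  var_g / (var_g + mean_vd / 2)
}
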