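#' REML fit of the single-kernel testcross model (PBLUP / GBLUP)
#'
#' Fits `y = X beta + t + e` on the calibration lines, where `y` holds the
#' stage-2 testcross BLUEs, `X` codes the selection-cycle fixed effect
#' (reference-level coding, earliest cycle as reference), `t ~ N(0, K
#' sigma_k^2)` with `K` the expected (pedigree) or realized (marker) kinship
#' kernel, and `e ~ N(0, I sigma_e^2)`. The restricted likelihood is profiled
#' in the variance ratio `lambda = sigma_e^2 / sigma_k^2` via one
#' eigendecomposition of the calibration-set kernel and maximized by a
#' derivative-free bounded search over `log lambda` in `[log 1e-6, log 1e6]`
#' (tolerance 1e-8; boundary solutions are flagged, not errored).
#'
#' BLUPs for all lines — including unphenotyped ones — are the conditional
#' means `K[all, CS] (K[CS, CS] + lambda I)^{-1} (y - X beta)`. Cycles absent
#' from the calibration set inherit the reference fixed-effect value (flagged
#' in `inestimable_cycles`); correlation-based accuracies are unaffected by
#' this within-cycle constant.
#'
#' If the calibration kernel is not positive semidefinite, a minimal diagonal
#' ridge (at least 1e-6) is added and recorded in `ridge`; a ridge above 1e-3
#' triggers a warning.
#'
#' @param blues data.frame with `line_id`, `cycle`, `blue`; rows for
#'   calibration lines must have finite `blue` (other lines may be `NA` —
#'   their cycles are still used for prediction).
#' @param kernel kinship matrix covering `all_ids`.
#' @param cs_ids phenotyped calibration line ids.
#' @param all_ids lines for which BLUPs are required (default: all kernel
#'   rows).
#' @param lambda fix the variance ratio instead of estimating it (used by the
#'   oracle-equivalence checks).
#' @param eigen_cs optional precomputed `eigen()` of the calibration-set
#'   kernel (in `cs_ids` order), reused across traits by the CV engine.
#' @return Object of class `blup_fit`: `beta` (coefficients), `cycle_values`
#'   (fixed-effect value per cycle), `var_kernel`, `var_resid`,
#'   `reml_loglik`, `lambda`, `blups` (named, over `all_ids`), `converged`,
#'   `boundary`, `ridge`, `inestimable_cycles`, plus the ids and cycle map.
#' @export
reml_fit <- function(blues, kernel, cs_ids, all_ids = rownames(kernel),
                     lambda = NULL, eigen_cs = NULL) {
  stopifnot(all(c("line_id", "cycle", "blue") %in% names(blues)))
  if (anyDuplicated(blues$line_id)) stop("duplicate line_id in blues")
  missing_k <- setdiff(all_ids, rownames(kernel))
  if (length(missing_k))
    stop("kernel does not cover ids: ",
         paste(utils::head(missing_k, 5), collapse = ", "))
  if (!all(cs_ids %in% all_ids)) stop("cs_ids must be a subset of all_ids")
  cyc_map <- stats::setNames(as.character(blues$cycle), blues$line_id)
  y <- blues$blue[match(cs_ids, blues$line_id)]
  if (any(!is.finite(y))) stop("non-finite response for calibration lines")
  n <- length(y)
  cyc_cs <- factor(cyc_map[cs_ids],
                   levels = sort(unique(as.character(blues$cycle))))
  present <- levels(cyc_cs)[levels(cyc_cs) %in% cyc_cs]
  cyc_cs <- factor(as.character(cyc_cs), levels = present)
  if (any(table(cyc_cs) < 2))
    stop("need >= 2 phenotyped lines per represented cycle")
  X <- if (length(present) > 1) stats::model.matrix(~cyc_cs)
       else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  p <- ncol(X)

  eg <- if (!is.null(eigen_cs)) eigen_cs else {
    Kcs <- kernel[cs_ids, cs_ids, drop = FALSE]
    eigen((Kcs + t(Kcs)) / 2, symmetric = TRUE)
  }
  d <- eg$values
  ridge <- 0
  if (min(d) < 1e-10) {
    ridge <- max(1e-6, 1e-8 - min(d))
    if (ridge > 1e-3)
      warning("kernel far from positive semidefinite: ridge = ",
              signif(ridge, 3))
    d <- d + ridge
  }
  Q <- eg$vectors
  yt <- drop(crossprod(Q, y))
  Xt <- crossprod(Q, X)

  profile <- function(lam) {
    w <- 1 / (d + lam)
    XtW <- Xt * w
    XWX <- crossprod(Xt, XtW)
    ch <- chol(XWX)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtW, yt)))
    r <- yt - drop(Xt %*% beta)
    rss <- sum(w * r^2)
    sigma2k <- max(rss / (n - p), .Machine$double.eps)
    m2ll <- (n - p) * log(sigma2k) + sum(log(d + lam)) +
      2 * sum(log(diag(ch))) + (n - p)
    list(beta = beta, sigma2k = sigma2k, m2ll = m2ll, wr = w * r)
  }

  lo <- log(1e-6); hi <- log(1e6)
  boundary <- FALSE
  if (is.null(lambda)) {
    opt <- stats::optimize(function(ll) profile(exp(ll))$m2ll, c(lo, hi),
                           tol = 1e-8)
    lambda <- exp(opt$minimum)
    boundary <- opt$minimum < lo + 1e-4 || opt$minimum > hi - 1e-4
  }
  pr <- profile(lambda)
  beta <- stats::setNames(drop(pr$beta), colnames(X))
  # fixed-effect value per cycle under reference coding
  all_cycles <- sort(unique(as.character(blues$cycle)))
  cycle_values <- stats::setNames(rep(beta[1], length(all_cycles)), all_cycles)
  for (cv in present[-1])
    cycle_values[cv] <- beta[1] + beta[paste0("cyc_cs", cv)]
  inestimable <- setdiff(all_cycles, present)

  # (K_cs + lambda I)^-1 (y - X beta) back in the original basis
  alpha <- drop(Q %*% pr$wr)
  blups <- drop(kernel[all_ids, cs_ids, drop = FALSE] %*% alpha)
  names(blups) <- all_ids

  structure(list(beta = beta,
                 cycle_values = cycle_values,
                 var_kernel = pr$sigma2k,
                 var_resid = lambda * pr$sigma2k,
                 reml_loglik = -0.5 * pr$m2ll,
                 lambda = lambda,
                 blups = blups,
                 converged = TRUE,
                 boundary = boundary,
                 ridge = ridge,
                 inestimable_cycles = inestimable,
                 cs_ids = cs_ids,
                 all_ids = all_ids,
                 cycle_map = cyc_map),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("<blup_fit> n_cs = %d, var_kernel = %.4g, var_resid = %.4g, lambda = %.4g%s\n",
              length(x$cs_ids), x$var_kernel, x$var_resid, x$lambda,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Predict testcross values for validation lines
#'
#' `Qhat_i = cycle fixed-effect value + BLUP_i`; the BLUP component is
#' returned separately since Pearson-correlation accuracies are invariant to
#' the within-cycle constant.
#'
#' @param fit a [reml_fit()] result.
#' @param vs_ids validation line ids (subset of the fit's `all_ids`, disjoint
#'   from the calibration set).
#' @return data.frame `line_id`, `cycle`, `blup`, `fixed`, `predicted`.
#' @export
predict_testcross <- function(fit, vs_ids) {
  stopifnot(inherits(fit, "blup_fit"))
  bad <- setdiff(vs_ids, fit$all_ids)
  if (length(bad))
    stop("validation lines without kernel rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (length(intersect(vs_ids, fit$cs_ids)))
    stop("validation lines overlap the calibration set")
  cyc <- fit$cycle_map[vs_ids]
  fixed <- fit$cycle_values[cyc]
  blup <- fit$blups[vs_ids]
  data.frame(line_id = vs_ids, cycle = cyc, blup = unname(blup),
             fixed = unname(fixed), predicted = unname(fixed + blup),
             stringsAsFactors = FALSE)
}

#' Dense Henderson mixed-model-equation oracle
#'
#' Assembles and solves Henderson's MME
#' `[X'X, X'Z; Z'X, Z'Z + lambda K^-1] [beta; u] = [X'y; Z'y]`
#' directly for small problems. Exists solely to cross-check the
#' eigendecomposition path of [reml_fit()] and [predict_testcross()] at a
#' fixed variance ratio; it is exact for any incidence `Z`, including columns
#' for unphenotyped lines.
#'
#' @param y response vector (length n).
#' @param X fixed-effect design matrix (n x p, full column rank).
#' @param Z random-effect incidence matrix (n x q).
#' @param kernel q x q covariance kernel (invertible after at most a tiny
#'   ridge supplied by the caller).
#' @param lambda variance ratio `sigma_e^2 / sigma_k^2`.
#' @return List `beta`, `effects`.
#' @export
solve_mme_oracle <- function(y, X, Z, kernel, lambda) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  stopifnot(nrow(X) == length(y), nrow(Z) == length(y),
            ncol(Z) == nrow(kernel))
  Kinv <- tryCatch(solve(kernel), error = function(e)
    stop("kernel is singular; add a ridge before calling the oracle"))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Kinv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("singular mixed-model coefficient matrix"))
  list(beta = sol[seq_len(ncol(X))],
       effects = sol[-seq_len(ncol(X))])
}
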