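#' Expected kinship matrix from an additive relationship matrix
#'
#' Elementwise halving, `K = 0.5 A`; K is the covariance kernel of the
#' pedigree-based (PBLUP) testcross model. Self-kinship of partially inbred
#' lines lies in `[0.5, 1]`.
#'
#' @param A relationship matrix from [build_A()].
#' @return Kinship matrix with `flavor` attribute `"K_expected"`.
#' @export
expected_kinship <- function(A) {
  if (!identical(attr(A, "flavor"), "A"))
    stop("expected_kinship() takes an A matrix (flavor \"A\")")
  K <- 0.5 * A
  attr(K, "flavor") <- "K_expected"
  K
}

#' Realized kinship matrix from marker data
#'
#' Marker-based analogue of the expected kinship: dosages are column-centered
#' by twice the observed allele frequency and
#' `U = 0.5 * W W' / (2 * sum_j p_j (1 - p_j))`,
#' i.e. half the usual genomic relationship matrix, so that U is on the
#' kinship scale and can replace K in an otherwise identical mixed model.
#' Allele frequencies are computed once from all lines in `G` (calibration and
#' validation together), so U does not change across cross-validation
#' scenarios. Monomorphic markers carry no information and are dropped.
#'
#' @param G a [genotypes()] object without missing values.
#' @return Kinship matrix with `flavor` attribute `"U_realized"`.
#' @export
realized_kinship <- function(G) {
  if (anyNA(G$dosage)) stop("genotypes contain missing values; impute first")
  p <- allele_freq(G)
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least two polymorphic markers")
  W <- sweep(G$dosage[, poly, drop = FALSE], 2, 2 * p[poly])
  U <- 0.5 * tcrossprod(W) / (2 * sum(p[poly] * (1 - p[poly])))
  attr(U, "flavor") <- "U_realized"
  U
}

#' Mean maximum kinship between a validation and a calibration set
#'
#' For every validation line the maximum realized kinship to any calibration
#' line, `U_max,i = max_j U_ij` over `j` in CS, and the mean over the
#' validation set, `Ubar_max` — the relatedness diagnostic for a prediction
#' scenario.
#'
#' @param U kinship matrix covering both sets.
#' @param cs_ids,vs_ids disjoint line id vectors, subsets of `rownames(U)`.
#' @return List `u_max` (named per-VS-line maxima), `u_max_which` (the CS line
#'   attaining each maximum), `u_max_mean`, `cs_ids`, `vs_ids`.
#' @export
mean_max_kinship <- function(U, cs_ids, vs_ids) {
  if (!length(cs_ids) || !length(vs_ids))
    stop("calibration and validation sets must be non-empty")
  if (length(intersect(cs_ids, vs_ids)))
    stop("calibration and validation sets overlap")
  missing <- setdiff(c(cs_ids, vs_ids), rownames(U))
  if (length(missing))
    stop("ids missing from kinship matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- U[vs_ids, cs_ids, drop = FALSE]
  u_max <- apply(sub, 1, max)
  u_which <- cs_ids[apply(sub, 1, which.max)]
  list(u_max = u_max,
       u_max_which = stats::setNames(u_which, vs_ids),
       u_max_mean = mean(u_max),
       cs_ids = cs_ids, vs_ids = vs_ids)
}

#' Rogers' distance between lines
#'
#' Per marker, the Euclidean distance between the two lines' within-locus
#' allele-frequency vectors scaled by `1/sqrt(2)` — which for biallelic
#' dosages reduces to `|d_i - d_j| / 2` — averaged over markers. Distances lie
#' in `[0, 1]`: 0 for identical lines, 1 for lines homozygous for opposite
#' alleles at every marker.
#'
#' @param G a [genotypes()] object without missing values.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
rogers_distance <- function(G) {
  if (anyNA(G$dosage)) stop("genotypes contain missing values; impute first")
  D <- as.matrix(stats::dist(G$dosage, method = "manhattan")) /
    (2 * ncol(G$dosage))
  dimnames(D) <- list(rownames(G$dosage), rownames(G$dosage))
  D
}

#' Principal coordinate analysis (classical scaling)
#'
#' Gower's classical scaling of a distance matrix: double-center `-0.5 D^2`,
#' eigendecompose, and take coordinates from the top `k` non-negative
#' eigenvalues. All eigenvalues (including negative ones, which arise for
#' non-Euclidean distances) are reported; negative eigenvalues are excluded
#' from the coordinates. Wraps [stats::cmdscale()].
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of coordinate axes requested.
#' @return List `coordinates` (n x k', `k' <= k` columns, truncated with a
#'   warning if fewer than `k` eigenvalues are positive) and `eigenvalues`
#'   (all n).
#' @export
pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(D, k = min(k, n - 1), eig = TRUE))
  pts <- fit$points
  if (max(fit$eig) <= 1e-12)   # degenerate: all points coincide
    return(list(coordinates = matrix(0, n, k, dimnames = list(rownames(D), NULL)),
                eigenvalues = fit$eig))
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-12)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; coordinates truncated to ",
            min(n_pos, ncol(pts)), " axes")
    pts <- pts[, seq_len(min(n_pos, ncol(pts))), drop = FALSE]
  }
  list(coordinates = pts, eigenvalues = fit$eig)
}
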