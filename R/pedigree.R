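#' Validate a pedigree table
#'
#' A pedigree is a data.frame with columns `id`, `parent1`, `parent2`,
#' `selfing_x` (and optionally `cycle`). Records must be topologically ordered
#' (parents precede offspring, which also guarantees acyclicity), unknown
#' parents (`NA`) are allowed only as founders and are treated as unrelated
#' non-inbred, and `selfing_x >= 0`.
#'
#' @param ped pedigree data.frame.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "parent1", "parent2", "selfing_x") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate pedigree ids")
  if (any(ped$selfing_x < 0, na.rm = TRUE)) stop("negative selfing_x")
  if (any(is.na(ped$parent1) != is.na(ped$parent2)))
    stop("parents must be both known or both unknown")
  seen <- character(0)
  for (i in seq_len(nrow(ped))) {
    p <- c(ped$parent1[i], ped$parent2[i])
    p <- p[!is.na(p)]
    if (any(p == ped$id[i]))
      stop("cyclic pedigree: ", ped$id[i], " is its own parent")
    if (!all(p %in% seen))
      stop("pedigree not topologically ordered (or cyclic) at id ", ped$id[i])
    seen <- c(seen, ped$id[i])
  }
  invisible(ped)
}

#' Additive relationship matrix with selfing-generation diagonal
#'
#' Off-diagonal elements follow the standard tabular method on the
#' selfing-free pedigree, `A_ij = 0.5 (A_{i,g(j)} + A_{i,h(j)})`, with unknown
#' parents contributing zero. The diagonal for a line with `x` recorded
#' selfing generations is replaced by
#' `A_ii = sum_{S=0}^{x} (1/2)^S + A_gh (1/2)^{x+1}`,
#' where `A_gh` is the relationship between the line's parents. This models
#' single-seed-descent inbreds without carrying the intermediate selfing
#' generations in the pedigree: for a founder (`x = 0`, unknown parents) the
#' formula collapses to 1, and for `x = 1` with unrelated non-inbred parents
#' to 1.5.
#'
#' @param ped a pedigree table (see [validate_pedigree()]).
#' @return Symmetric relationship matrix with `flavor` attribute `"A"`.
#' @export
build_A <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  gi <- match(ped$parent1, ids)
  hi <- match(ped$parent2, ids)
  for (j in seq_len(n)) {
    g <- gi[j]; h <- hi[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      aig <- if (is.na(g)) 0 else A[prev, g]
      aih <- if (is.na(h)) 0 else A[prev, h]
      A[prev, j] <- A[j, prev] <- 0.5 * (aig + aih)
    }
    a_gh <- if (is.na(g) || is.na(h)) 0 else A[g, h]
    x <- ped$selfing_x[j]
    A[j, j] <- sum(0.5^(0:x)) + a_gh * 0.5^(x + 1)
  }
  attr(A, "flavor") <- "A"
  A
}

#' Expanded-pedigree tabular oracle for [build_A()]
#'
#' Expands every line's `selfing_x` generations into explicit selfing
#' individuals (S0 with the recorded parents, then S1 = S0 x S0, ...) and runs
#' the classical tabular method with the textbook diagonal
#' `A_jj = 1 + 0.5 A_{g(j)h(j)}`. The submatrix for the original ids must
#' equal [build_A()] exactly; the function exists as an independent
#' cross-check and is used by the validation suite.
#'
#' @param ped a pedigree table.
#' @return Relationship matrix restricted to the original pedigree ids.
#' @export
build_A_expanded <- function(ped) {
  validate_pedigree(ped)
  rows <- list()
  final_name <- character(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    x <- ped$selfing_x[i]
    if (x == 0L || is.na(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = ped$id[i], parent1 = ped$parent1[i], parent2 = ped$parent2[i],
        stringsAsFactors = FALSE)
      final_name[i] <- ped$id[i]
    } else {
      prev <- paste0(ped$id[i], "::S0")
      rows[[length(rows) + 1L]] <- data.frame(
        id = prev, parent1 = ped$parent1[i], parent2 = ped$parent2[i],
        stringsAsFactors = FALSE)
      for (s in seq_len(x)) {
        nm <- if (s == x) ped$id[i] else paste0(ped$id[i], "::S", s)
        rows[[length(rows) + 1L]] <- data.frame(
          id = nm, parent1 = prev, parent2 = prev, stringsAsFactors = FALSE)
        prev <- nm
      }
      final_name[i] <- prev
    }
  }
  ep <- do.call(rbind, rows)
  n <- nrow(ep)
  ids <- ep$id
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  gi <- match(ep$parent1, ids)
  hi <- match(ep$parent2, ids)
  for (j in seq_len(n)) {
    g <- gi[j]; h <- hi[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      aig <- if (is.na(g)) 0 else A[prev, g]
      aih <- if (is.na(h)) 0 else A[prev, h]
      A[prev, j] <- A[j, prev] <- 0.5 * (aig + aih)
    }
    A[j, j] <- 1 + if (is.na(g) || is.na(h)) 0 else 0.5 * A[g, h]
  }
  A[ped$id, ped$id]
}

#' Gene-drop (IBD simulation) estimate of the relationship matrix
#'
#' Monte-Carlo oracle for [build_A()]: founder alleles are labelled uniquely
#' and dropped through the pedigree, including each line's recorded selfing
#' generations (single-seed descent). The additive relationship is estimated
#' as twice the identity-by-descent kinship; diagonals as `1 + F` with `F`
#' the probability the line's two alleles are IBD. Intended for small
#' pedigrees (<= a few dozen individuals).
#'
#' @param ped a pedigree table.
#' @param n_rep number of independent gene drops.
#' @param seed integer seed.
#' @return Estimated relationship matrix (same order as `ped$id`).
#' @export
gene_drop_A <- function(ped, n_rep = 1e5, seed = 1L) {
  validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  gi <- match(ped$parent1, ids)
  hi <- match(ped$parent2, ids)
  with_stream(seed, "gene_drop", {
    a1 <- matrix(0L, n_rep, n)
    a2 <- matrix(0L, n_rep, n)
    pick <- function(x, y) {
      sel <- stats::rbinom(n_rep, 1L, 0.5) == 1L
      out <- x
      out[sel] <- y[sel]
      out
    }
    next_allele <- 1L
    for (j in seq_len(n)) {
      if (is.na(gi[j])) {
        a1[, j] <- next_allele
        a2[, j] <- next_allele + 1L
        next_allele <- next_allele + 2L
      } else {
        u <- pick(a1[, gi[j]], a2[, gi[j]])
        v <- pick(a1[, hi[j]], a2[, hi[j]])
        x <- ped$selfing_x[j]
        if (x > 0L) for (s in seq_len(x)) {
          u2 <- pick(u, v)
          v2 <- pick(u, v)
          u <- u2; v <- v2
        }
        a1[, j] <- u
        a2[, j] <- v
      }
    }
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      A[i, i] <- 1 + mean(a1[, i] == a2[, i])
      if (i < n) for (j in seq((i + 1L), n)) {
        kin <- 0.25 * (colMeans(cbind(a1[, i] == a1[, j], a1[, i] == a2[, j],
                                      a2[, i] == a1[, j], a2[, i] == a2[, j])))
        A[i, j] <- A[j, i] <- 2 * sum(kin)
      }
    }
    A
  })
}
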