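# Zero-truncated Poisson with a given mean: solve lambda/(1 - exp(-lambda)) = m
# for the underlying rate, then sample by inversion restricted to k >= 1.
ztpois_rate <- function(mean_target) {
  stopifnot(mean_target > 1)
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean_target,
                 lower = 1e-8, upper = 10 * mean_target, tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate the multi-cycle breeding program: pedigree and true genotypes
#'
#' For each selection cycle a parent subset is chosen from the overall pool
#' such that consecutive cycles share a number of parents drawn uniformly from
#' `common_parents_range`. Crosses between distinct parents of the cycle's pool
#' are drawn, each yielding a zero-truncated Poisson number of progeny (capped
#' at `max_lines_per_cross`), until the cycle's line quota is filled. Every
#' progeny is an independent F1 of its cross selfed twice by single-seed
#' descent (S0 -> S1 -> S2); the reported genotype is that of the S2 plant.
#' The pedigree records each line with its two parents and the configured
#' selfing-generation count `selfing_x` (default 1: the relationship matrix
#' models lines at x = 1, see [sim_config()]).
#'
#' @param config a [sim_config()].
#' @param founders optional precomputed [simulate_founders()] result.
#' @return List with `pedigree` (data.frame `id`, `parent1`, `parent2`,
#'   `selfing_x`, `cycle`; founder parents first with unknown parents `NA`),
#'   `genotypes` (a [genotypes()] object of true S2 dosages, no missing
#'   values), `cycle_assignment` (named integer vector line -> cycle),
#'   `parent_pools` (list of per-cycle parent id vectors) and `founders`.
#' @export
simulate_breeding_program <- function(config, founders = NULL) {
  validate_sim_config(config)
  if (is.null(founders)) founders <- simulate_founders(config)
  mi <- map_index(founders$map)
  all_parents <- rownames(founders$h1)
  m_pool <- parents_per_cycle(config)

  pools <- with_stream(config$seed, "parent_pools", {
    pools <- vector("list", config$n_cycles)
    unused <- all_parents
    for (cy in seq_len(config$n_cycles)) {
      if (cy == 1L) {
        pools[[cy]] <- sample(all_parents, m_pool)
      } else {
        k <- sample(seq(config$common_parents_range[1],
                        config$common_parents_range[2]), 1L)
        keep <- sample(pools[[cy - 1L]], k)
        fresh_pool <- setdiff(unused, pools[[cy - 1L]])
        n_new <- m_pool - k
        if (length(fresh_pool) >= n_new) {
          new <- sample(fresh_pool, n_new)
        } else {
          # pool of never-used parents exhausted: re-admit parents from
          # earlier cycles (but never the previous cycle, so the configured
          # consecutive overlap stays exact)
          recycled <- setdiff(all_parents, c(pools[[cy - 1L]], fresh_pool))
          short <- n_new - length(fresh_pool)
          if (short > length(recycled))
            stop("invalid configuration: parent pool too small for the ",
                 "requested cycle structure")
          new <- c(fresh_pool, sample(recycled, short))
        }
        pools[[cy]] <- c(keep, new)
      }
      unused <- setdiff(unused, pools[[cy]])
    }
    pools
  })

  lam <- ztpois_rate(config$mean_lines_per_cross)
  crosses <- with_stream(config$seed, "crosses", {
    out <- vector("list", config$n_cycles)
    for (cy in seq_len(config$n_cycles)) {
      need <- config$lines_per_cycle
      cs <- list()
      while (need > 0L) {
        pair <- sample(pools[[cy]], 2L)
        np <- min(rztpois(1L, lam), config$max_lines_per_cross, need)
        cs[[length(cs) + 1L]] <- list(p1 = pair[1], p2 = pair[2], n = np)
        need <- need - np
      }
      out[[cy]] <- cs
    }
    out
  })

  n_lines <- config$n_cycles * config$lines_per_cycle
  n_snps <- config$n_snps
  dosage <- matrix(NA_real_, n_lines, n_snps)
  line_ids <- character(n_lines)
  ped_rows <- vector("list", n_lines)
  cyc <- integer(n_lines)
  i <- 0L
  for (cy in seq_len(config$n_cycles)) {
    with_stream(config$seed, paste0("meiosis/cycle", cy), {
      li <- 0L
      for (cr in crosses[[cy]]) {
        g1 <- match(cr$p1, all_parents); g2 <- match(cr$p2, all_parents)
        for (k in seq_len(cr$n)) {
          i <- i + 1L; li <- li + 1L
          id <- sprintf("C%d_L%03d", cy, li)
          # F1 (S0), then two generations of single-seed descent
          f1a <- sample_gamete(founders$h1[g1, ], founders$h2[g1, ], mi,
                               config$chrom_length_cM)
          f1b <- sample_gamete(founders$h1[g2, ], founders$h2[g2, ], mi,
                               config$chrom_length_cM)
          s1a <- sample_gamete(f1a, f1b, mi, config$chrom_length_cM)
          s1b <- sample_gamete(f1a, f1b, mi, config$chrom_length_cM)
          s2a <- sample_gamete(s1a, s1b, mi, config$chrom_length_cM)
          s2b <- sample_gamete(s1a, s1b, mi, config$chrom_length_cM)
          dosage[i, ] <- s2a + s2b
          line_ids[i] <- id
          cyc[i] <- cy
          ped_rows[[i]] <- data.frame(id = id, parent1 = cr$p1,
                                       parent2 = cr$p2,
                                       selfing_x = config$selfing_x,
                                       cycle = cy, stringsAsFactors = FALSE)
        }
      }
    })
  }
  dimnames(dosage) <- list(line_ids, founders$map$marker)
  used_parents <- sort(unique(unlist(lapply(ped_rows, function(r)
    c(r$parent1, r$parent2)))))
  ped <- rbind(
    data.frame(id = used_parents, parent1 = NA_character_,
               parent2 = NA_character_, selfing_x = 0L, cycle = NA_integer_,
               stringsAsFactors = FALSE),
    do.call(rbind, ped_rows))
  ca <- stats::setNames(cyc, line_ids)
  list(pedigree = ped,
       genotypes = genotypes(dosage, founders$map),
       cycle_assignment = ca,
       parent_pools = pools,
       founders = founders)
}
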