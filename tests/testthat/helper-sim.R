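# Shared miniature configurations and data builders for the test suite.

tiny_config <- function(seed = 7, ...) {
  defaults <- list(
    n_cycles = 2, lines_per_cycle = 40, n_parents_total = 30,
    common_parents_range = c(3L, 5L), n_snps = 300,
    n_locations_per_cycle = 4, n_reps = c(GDY = 2L),
    target_h2 = c(GDY = 0.86), qtl_counts = c(GDY = 60L),
    qtl_effect_model = c(GDY = "polygenic"), block_size = 10,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Random HW genotypes (unrelated lines), used where pedigree structure is
# irrelevant.
random_genotypes <- function(n_lines, n_markers, p = NULL, seed = 1,
                             with_map = TRUE) {
  set.seed(seed)
  if (is.null(p)) p <- runif(n_markers, 0.1, 0.9)
  d <- matrix(rbinom(n_lines * n_markers, 2, rep(p, each = n_lines)),
              n_lines, n_markers,
              dimnames = list(sprintf("L%03d", seq_len(n_lines)),
                              sprintf("M%04d", seq_len(n_markers))))
  map <- if (with_map)
    data.frame(marker = colnames(d), chrom = "1R",
               pos_cM = sort(runif(n_markers, 0, 100)))
  else NULL
  genotypes(d, map)
}

# A small two-generation pedigree with known relationships, used across the
# relatedness tests.
toy_pedigree <- function() {
  data.frame(
    id = c("g", "h", "p", "A", "B", "C"),
    parent1 = c(NA, NA, NA, "g", "g", "g"),
    parent2 = c(NA, NA, NA, "h", "h", "p"),
    selfing_x = c(0L, 0L, 0L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

# Random valid pedigree for property tests: founders then offspring with
# random parents among earlier ids and random selfing counts.
random_pedigree <- function(n_founders, n_lines, max_x = 3, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("F%02d", seq_len(n_founders)),
           sprintf("X%02d", seq_len(n_lines)))
  ped <- data.frame(id = ids, parent1 = NA_character_,
                    parent2 = NA_character_, selfing_x = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_lines)) {
    j <- n_founders + i
    pool <- ids[seq_len(j - 1)]
    ped$parent1[j] <- sample(pool, 1)
    ped$parent2[j] <- sample(setdiff(pool, ped$parent1[j]), 1)
    ped$selfing_x[j] <- sample(0:max_x, 1)
  }
  ped
}

# Stage-1-like adjusted means generated directly from known variance
# components (bypassing plot simulation), for stage-2 recovery tests.
simulated_adjusted_means <- function(n_lines = 100, n_lt = 4, var_g = 15,
                                     var_lt = 10, var_gxlt = 7.5,
                                     se2_range = c(0.5, 3), seed = 1,
                                     cycle = 1, trait = "GDY") {
  set.seed(seed)
  lines <- sprintf("S%03d", seq_len(n_lines))
  g <- rnorm(n_lines, 0, sqrt(var_g))
  lt <- rnorm(n_lt, 0, sqrt(var_lt))
  d <- expand.grid(line_id = lines, loc_tester = sprintf("LT%d", seq_len(n_lt)),
                   stringsAsFactors = FALSE)
  d$se <- sqrt(runif(nrow(d), se2_range[1], se2_range[2]))
  d$blue <- 50 + g[match(d$line_id, lines)] +
    lt[match(d$loc_tester, sprintf("LT%d", seq_len(n_lt)))] +
    rnorm(nrow(d), 0, sqrt(var_gxlt)) + rnorm(nrow(d), 0, d$se)
  d$cycle <- cycle
  d$trait <- trait
  attr(d, "true_g") <- stats::setNames(g, lines)
  d
}
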