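#!/usr/bin/env Rscript
# Stage 4: relationship matrices and germplasm structure. Builds the additive
# relationship matrix A from the pedigree with the selfing-adjusted diagonal
# (lines at x = 1), the expected kinship K = A/2, and the realized kinship U
# from the QC'd markers (half the VanRaden genomic relationship, frequencies
# from all lines jointly); then the Rogers-distance principal coordinate
# analysis of the four cycles.

library(ryegp)

data_dir <- "results/data"
out <- "results/relatedness"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ped <- read_pedigree_csv(file.path(data_dir, "pedigree.csv"))
G <- read_genotypes_tsv("results/qc/genotypes_qc.tsv",
                        file.path(data_dir, "map.csv"))
state <- readRDS(file.path(data_dir, "sim_state.rds"))
ca <- state$cycle_assignment
lines <- names(ca)

A <- build_A(ped)
K <- expected_kinship(A)
U <- realized_kinship(G)
write_kinship_tsv(K[lines, lines], file.path(out, "kinship_K.tsv"))
write_kinship_tsv(U[lines, lines], file.path(out, "kinship_U.tsv"))

off <- upper.tri(K[lines, lines])
cat(sprintf("cor(K, U) over line pairs: %.3f\n",
            cor(K[lines, lines][off], U[lines, lines][off])))

# PCoA of Rogers' distances (germplasm structure, Fig-S2-style coordinates)
D <- rogers_distance(G)
pc <- pcoa(D[lines, lines], k = 4)
coords <- data.frame(line_id = lines, cycle = ca[lines],
                     pc$coordinates[lines, ])
write.csv(coords, file.path(out, "pcoa_coordinates.csv"), row.names = FALSE)
ev <- pc$eigenvalues
cat(sprintf("PCoA: first four axes explain %.1f%% of the positive eigenvalue mass\n",
            100 * sum(ev[1:4]) / sum(ev[ev > 0])))

# relatedness diagnostic: an 80/20 within-cycle split vs across-cycle pairs
set.seed(derive_seed(1L, "umax_demo"))
rows <- list()
for (cy in sort(unique(ca))) {
  ids <- names(ca)[ca == cy]
  vs <- sample(ids, length(ids) / 5)
  rows[[length(rows) + 1L]] <- data.frame(
    comparison = sprintf("within cycle %d", cy),
    u_max_mean = mean_max_kinship(U, setdiff(ids, vs), vs)$u_max_mean)
  for (cs_cy in setdiff(sort(unique(ca)), cy))
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = sprintf("cycle %d -> %d", cs_cy, cy),
      u_max_mean = mean_max_kinship(U, names(ca)[ca == cs_cy], vs)$u_max_mean)
}
umax <- do.call(rbind, rows)
write.csv(umax, file.path(out, "umax_summary.csv"), row.names = FALSE)
cat("\nMean maximum realized kinship of validation lines to the calibration set:\n")
print(umax, digits = 3, row.names = FALSE)
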