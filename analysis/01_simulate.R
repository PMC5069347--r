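#!/usr/bin/env Rscript
# Stage 1 of the analysis workflow: generate the synthetic multi-cycle hybrid
# rye breeding program at its default desk scale (4 cycles x 260 S2 lines from
# crosses of a 203-parent pool, 2000 SNPs on 7 chromosomes, testcross trials
# for a polygenic yield-like trait, an oligogenic height-like trait and a
# single-replicate oligogenic kernel-weight-like trait), corrupt the
# genotypes with realistic missingness, and write all raw data tables.

library(ryegp)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cfg <- sim_config(seed = seed)
print(cfg)

sim <- simulate_breeding_program(cfg)
arch <- make_trait_architecture(cfg, sim$genotypes)
plots <- simulate_testcross_trials(cfg, sim, arch)
G_raw <- corrupt_genotypes(sim$genotypes, missing_rate = 0.02,
                           seed = derive_seed(seed, "corrupt"))

write_pedigree_csv(sim$pedigree, file.path(out, "pedigree.csv"))
write_genotypes_tsv(G_raw, file.path(out, "genotypes_raw.tsv"))
write_map_csv(sim$genotypes$map, file.path(out, "map.csv"))
write_plots_csv(plots, file.path(out, "plots.csv"))
saveRDS(list(config = cfg, architecture = arch,
             cycle_assignment = sim$cycle_assignment),
        file.path(out, "sim_state.rds"))

cat(sprintf("\nSimulated %d S2 lines in %d cycles (%d pedigree records),\n",
            length(sim$cycle_assignment), cfg$n_cycles, nrow(sim$pedigree)))
cat(sprintf("%d plot records over %d traits; %.1f%% genotype entries masked.\n",
            nrow(plots), length(unique(plots$trait)),
            100 * mean(is.na(G_raw$dosage))))
for (cy in 2:cfg$n_cycles)
  cat(sprintf("cycles %d-%d share %d parents\n", cy - 1, cy,
              length(intersect(sim$parent_pools[[cy - 1]],
                               sim$parent_pools[[cy]]))))
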