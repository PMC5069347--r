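#!/usr/bin/env Rscript
# Stage 5: the cross-validation study. One shared 10 x 5-fold plan per cycle
# drives every scenario: CV1 (within cycle), CV2.1 and CV2.3 (across cycles,
# one or three calibration cycles, forward and backward), and CV3 (all four
# cycles minus the validation fold, calibration sizes 208-832). GBLUP uses
# the realized kinship U, PBLUP the expected kinship K; accuracies are
# predictive abilities divided by the square root of the validation cycle's
# heritability. Writes fold-level results and the figure/table analogues.

library(ryegp)

out <- "results/cv"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

state <- readRDS("results/data/sim_state.rds")
ca <- state$cycle_assignment
lines <- names(ca)
blues <- read.csv("results/two_stage/blues.csv", stringsAsFactors = FALSE)
vc <- read.csv("results/two_stage/table1_analogue.csv",
               stringsAsFactors = FALSE)
K <- read_kinship_tsv("results/relatedness/kinship_K.tsv", flavor = "K_expected")
U <- read_kinship_tsv("results/relatedness/kinship_U.tsv", flavor = "U_realized")

traits <- c("GDY", "PHT")   # the polygenic / oligogenic contrast
plan <- make_folds(ca, n_reps = 10, n_folds = 5,
                   seed = derive_seed(1L, "folds"))
kernels <- list(GBLUP = U, PBLUP = K)
h2 <- vc[, c("cycle", "trait", "h2")]

res <- rbind(
  run_cv(blues, kernels, h2, plan, scenarios = c("CV1", "CV2.1", "CV2.3"),
         u_matrix = U, traits = traits),
  run_cv(blues, kernels["GBLUP"], h2, plan, scenarios = "CV3",
         u_matrix = U, traits = traits))
write.csv(res, file.path(out, "cv_results.csv"), row.names = FALSE)

sm <- summarize_cv(res)
write.csv(sm$summary, file.path(out, "cv_summary.csv"), row.names = FALSE)
write.csv(sm$fig3_matrix, file.path(out, "fig3_matrix.csv"), row.names = FALSE)
write.csv(sm$fig4_pairs, file.path(out, "fig4_pairs.csv"), row.names = FALSE)
write.csv(sm$fig5_boxdata, file.path(out, "fig5_boxdata.csv"),
          row.names = FALSE)

# Table-2 analogue: CV3 GBLUP accuracy by calibration-set size
t2 <- sm$summary[sm$summary$scenario == "CV3" & sm$summary$model == "GBLUP",
                 c("trait", "n_cs", "mean")]
t2 <- reshape(t2, idvar = "n_cs", timevar = "trait", direction = "wide")
names(t2) <- sub("mean\\.", "", names(t2))
write.csv(t2, file.path(out, "table2_analogue.csv"), row.names = FALSE)

cat("\nCV3 (joint within/across-cycle) GBLUP accuracy by calibration size:\n")
print(t2, digits = 3, row.names = FALSE)
cat("\nWithin-cycle vs forward across-cycle accuracy (GBLUP / PBLUP):\n")
fwd <- res[res$scenario == "CV2.1" & res$direction == "forward", ]
for (tr in traits)
  cat(sprintf(
    "  %s: CV1 %.2f / %.2f  |  CV2.1 forward %.2f / %.2f\n", tr,
    mean(res$accuracy[res$scenario == "CV1" & res$model == "GBLUP" &
                        res$trait == tr], na.rm = TRUE),
    mean(res$accuracy[res$scenario == "CV1" & res$model == "PBLUP" &
                        res$trait == tr], na.rm = TRUE),
    mean(fwd$accuracy[fwd$model == "GBLUP" & fwd$trait == tr], na.rm = TRUE),
    mean(fwd$accuracy[fwd$model == "PBLUP" & fwd$trait == tr], na.rm = TRUE)))
cat("\nAccuracy grows steadily with calibration-set size when cycles are\n")
cat("aggregated, and the GBLUP-PBLUP gap widens sharply across the cycle\n")
cat("boundary, where expected relationships carry little information; how\n")
cat("the gap compares between the two architectures varies with the QTL\n")
cat("realization (see the methods vignette).\n")
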