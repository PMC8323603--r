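#!/usr/bin/env Rscript
# Trains the packaged logistic accuracy model on a fixed-seed simulator grid
# and writes inst/extdata/accuracy_glm.txt. Run from the repository root
# after installing the package. One-time, deterministic.

library(contigDamage)

dir.create("scratch", showWarnings = FALSE)

grid <- simulateGrid(
    damage = c(0, 0.02, 0.05, 0.10, 0.14, 0.20),
    coverage = c(1, 3, 8, 20, 60, 150),
    contigLength = c(1000, 3000, 10000, 30000),
    gc = c(0.31, 0.47, 0.72),
    replicates = 1L,
    baseSeed = 20210L,
    prefix = "scratch/accuracy_training",
    seqError = 0.001)

res <- analyzeDamage(grid$sam, fasta = grid$fasta, accuracyModel = NULL)
training <- buildTrainingTable(grid$truth, as.data.frame(res))
cat(sprintf("training rows: %d (correct: %d, incorrect: %d)\n",
            nrow(training), sum(training$correct), sum(!training$correct)))

model <- fitAccuracyGLM(training,
                        predictors = c("damage", "coverage",
                                       "contig_length"),
                        repeats = 10L, seed = 42L, aggregate = "mean")
model@provenance <- sprintf(
    "simulator grid: damage 0-0.2 (6 levels) x coverage 1-150 (6) x length 1-30 kb (4) x GC 0.31/0.47/0.72, seed 20210, %d labelled contigs, 10 balanced down-sampling repeats, mean coefficients",
    nrow(training))
show(model)
writeAccuracyModel(model, "inst/extdata/accuracy_glm.txt")
cat("wrote inst/extdata/accuracy_glm.txt\n")
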