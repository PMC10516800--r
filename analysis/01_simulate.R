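#!/usr/bin/env Rscript
# Stage 1: draw the synthetic two-group study.
#
# Emulates the study design — 2 groups x 10 subjects x 176 ROIs — with
# block-correlated uptake within each structure and seven planted
# between-group edge differences (four caudoputamen-motor couplings present
# only in the exercise group, three thalamus-prefrontal couplings present
# only in the control group). Writes the group tables, the registry used,
# and the planted ground truth under results/data/.

suppressPackageStartupMessages(library(metaconn))

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(seed = seed)
write_registry(study$registry, file.path(out, "registry.csv"))
write_uptake(study$control, file.path(out, "control.csv"))
write_uptake(study$exercise, file.path(out, "exercise.csv"))
write.csv(study$truth, file.path(out, "planted_truth.csv"), row.names = FALSE)

cat(sprintf("simulated %d + %d subjects over %d ROIs (seed %d)\n",
            nrow(study$control$values), nrow(study$exercise$values),
            ncol(study$control$values), seed))
cat(sprintf("planted ground truth: %d group-difference edges\n",
            nrow(study$truth)))
cat("wrote results/data/{registry,control,exercise,planted_truth}.csv\n")
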