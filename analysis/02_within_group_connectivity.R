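#!/usr/bin/env Rscript
# Stage 2: within-group metabolic connectivity.
#
# For each group: global (proportional) scaling, the cross-subject Pearson
# correlation matrix with Fisher z transform, the n-iteration jackknife
# reliability criterion for edges, and the signed connectivity-density
# table over all structure pairs. Mirrors the within-group half of the
# published analysis.

suppressPackageStartupMessages(library(metaconn))

dat <- "results/data"; out <- "results/connectivity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
reg <- load_registry(file.path(dat, "registry.csv"))

for (g in c("control", "exercise")) {
  tab <- global_scale(read_uptake(file.path(dat, paste0(g, ".csv")), reg, g))
  res <- pearson_matrix(tab)
  write_matrix_csv(res$r, file.path(out, paste0(g, "_r.csv")))
  write_matrix_csv(res$z, file.path(out, paste0(g, "_z.csv")))
  edges <- reliable_edges_jackknife(tab, alpha = 0.05)
  write_edge_set(edges, file.path(out, paste0(g, "_edges.csv")))
  dens <- density_table(edges, reg)
  write.csv(dens, file.path(out, paste0(g, "_density.csv")), row.names = FALSE)

  within <- dens[dens$structure_a == dens$structure_b, ]
  cat(sprintf("%s: %d reliable edges (%d+, %d-)\n", g, nrow(edges),
              sum(edges$sign == "+"), sum(edges$sign == "-")))
  cat("  within-structure positive densities (%):\n")
  cat(sprintf("    %-5s %6.2f\n", within$structure_a, within$positive_density),
      sep = "")
}
cat("wrote results/connectivity/{control,exercise}_{r,z,edges,density}.csv\n")
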