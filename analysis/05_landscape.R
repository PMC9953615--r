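#!/usr/bin/env Rscript
# Stage 5: the coupled two-dimensional free-energy landscape over
# (conformation, lipid position), its least-energy (minimax) path from
# the closed/outer-leaflet corner to the open/inner-leaflet corner, and
# the barrier along that route. Renders the heat map with the path
# overlaid.

library(flipscape)

out <- "results/landscape"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

prof <- read.delim("results/cg_energy/profile.tsv")
bind <- read.delim("results/binding/binding.tsv")
offsets <- sort(unique(bind$offset))
nf <- nrow(prof)
bind_g <- matrix(NA_real_, nf, length(offsets))
for (r in seq_len(nrow(bind)))
  bind_g[bind$frame[r] + 1L, match(bind$offset[r], offsets)] <-
    bind$dg_bind[r]

land <- build_landscape(prof$profile, bind_g, offsets = offsets,
                        conf_labels = prof$frame)
j_start <- which.min(land$G[1, ])
j_end <- which.min(land$G[nf, ])
path <- least_energy_path(land, c(1, j_start), c(nf, j_end))

write.table(landscape_table(land), file.path(out, "landscape.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(step = seq_len(nrow(path$cells)),
                       frame = path$cells[, 1] - 1L,
                       offset = offsets[path$cells[, 2]],
                       G = land$G[path$cells]),
            file.path(out, "path.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

p <- plot_landscape(land, path)
if (!is.null(p))
  try(suppressMessages(ggplot2::ggsave(file.path(out, "landscape.png"),
                                       p, width = 7, height = 5,
                                       dpi = 150)), silent = TRUE)

cat(sprintf(paste0(
  "Coupled map %d x %d, calibrated to its reference cell; least-energy\n",
  "path: %d cells, barrier %.2f kcal/mol (peak at frame %d,\n",
  "offset %+d A). 1D conformational barrier for comparison: %.2f\n",
  "kcal/mol.\n"),
  nf, length(offsets), nrow(path$cells), path$barrier,
  path$peak[1] - 1, offsets[path$peak[2]],
  least_energy_path(matrix(prof$profile, ncol = 1),
                    c(1, 1), c(nf, 1))$barrier))
cat("Wrote", out, "\n")
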