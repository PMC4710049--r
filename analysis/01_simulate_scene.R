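#!/usr/bin/env Rscript

# Simulate the demonstration tissue section used by the downstream analysis
# scripts: a male-spinal-cord-like scene in which PCDH11X-expressing cells
# are enriched ventrally (3x) while PCDH11Y-expressing cells are spatially
# homogeneous. Writes the rendered channel TIFFs, the ground-truth spot
# table and the scene parameters under results/demo_scene/.

suppressPackageStartupMessages(library(xyspots))
out <- "results/demo_scene"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- scene_config(
  image_height = 800, image_width = 800, tissue_shape = "ellipse",
  n_cells = 2000, min_nucleus_separation = 11,
  nucleus_radius_mean = 4, nucleus_radius_sd = 0.4,
  class_proportions = c(no_signal = 0.87, x_only = 0.06,
                        y_only = 0.06, mixed = 0.01),
  spots_per_expressing_cell_mean = 1.5,
  ventral_x_enrichment = 3,
  spot_scatter_sd = 2, spot_sigma = 1.2, noise_sd = 0.01,
  genes = c(x = "PCDH11X", y = "PCDH11Y"), seed = 20260920L)

scene <- generate_scene(config)
channels <- render_scene(scene)

clip01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
for (nm in names(channels)) {
  write_image_tiff(clip01(channels[[nm]]), file.path(out, paste0(nm, ".tif")))
}
write_spot_table(scene$spots, file.path(out, "true_spots.csv"))
yaml::write_yaml(
  c(config[setdiff(names(config), c("class_proportions", "genes"))],
    list(class_proportions = as.list(config$class_proportions),
         genes = as.list(config$genes))),
  file.path(out, "scene_config.yaml"))

cls <- table(scene$nuclei$class)
cat("Simulated", config$n_cells, "cells:", nrow(scene$spots), "spots\n")
print(cls)
cat("Ground truth written to", out, "\n")
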