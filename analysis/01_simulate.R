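#!/usr/bin/env Rscript
# Simulate the histological raw material: a two-area laminar ribbon with a
# known border, rendered both as a profile matrix and as a binarized
# cell-body image between two cortical contours (flat and curved variants).
# Everything downstream works from these artifacts.

suppressPackageStartupMessages(library(cytoarch))
dir.create("results", showWarnings = FALSE)

seed <- 20260929L
models <- default_laminar_models(noise_sd = 0.03)
cat("Laminar models: agranular vs dysgranular, differing by 0.15 GLI in",
    "layers II and IV; GLI noise sd 0.03.\n")

## ribbon of 162 traverses with the border after traverse 76
ribbon <- render_ribbon(models, c(76, 86), depth_bins = 100, seed = seed)
write.csv(ribbon$profiles, "results/ribbon_profiles.csv", row.names = FALSE)
jsonlite::write_json(
  list(true_borders = ribbon$true_borders,
       area_labels = unique(ribbon$area_labels), seed = seed),
  "results/ribbon_truth.json", auto_unbox = TRUE)
cat(sprintf("Ribbon: %d traverses x %d depths, true border at %d.\n",
            nrow(ribbon$profiles), ncol(ribbon$profiles),
            ribbon$true_borders))

## binarized cell image of the same two areas (flat ribbon)
im <- render_gli_image(default_laminar_models(noise_sd = 0),
                       segment_px = c(76, 86) * 16, thickness_px = 320,
                       seed = seed)
write_cell_image(im$image, "results/cell_image_flat.png")
write.csv(im$outer, "results/contour_outer.csv", row.names = FALSE)
write.csv(im$inner, "results/contour_inner.csv", row.names = FALSE)
jsonlite::write_json(list(true_border_arcpos = im$true_border_arcpos,
                          thickness_px = 320, resolution_um_per_px = 1.02),
                     "results/cell_image_truth.json", auto_unbox = TRUE)
cat(sprintf("Flat cell image: %d x %d px, border at arc position %d px.\n",
            nrow(im$image), ncol(im$image), im$true_border_arcpos))

## curved variant exercising the Laplacian traverses
imc <- render_gli_image(default_laminar_models(noise_sd = 0),
                        segment_px = c(76, 86) * 16, thickness_px = 320,
                        curvature = 1 / 4000, seed = seed)
write_cell_image(imc$image, "results/cell_image_curved.png")
write.csv(imc$outer, "results/contour_outer_curved.csv", row.names = FALSE)
write.csv(imc$inner, "results/contour_inner_curved.csv", row.names = FALSE)
cat(sprintf("Curved cell image: %d x %d px (outer radius 4000 px).\n",
            nrow(imc$image), ncol(imc$image)))
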