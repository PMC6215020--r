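#!/usr/bin/env Rscript
# Step 1 — simulate the three nucleus-image panels and archive a small
# TIFF sample of each.
#
# The full pipelines (analysis/02) regenerate images on the fly from seeds,
# so this step only materializes a browsable sample: 3 nuclei per class per
# panel as 16-bit TIFFs with a manifest, plus the panel parameter tables.

suppressMessages(library(speckletex))

out <- "results/images"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panels <- list(enhancer = enhancer_panel_specs(),
               inhibitor = inhibitor_panel_specs(),
               os72 = os72_panel_specs())
seeds <- c(enhancer = 11L, inhibitor = 17L, os72 = 19L)

for (nm in names(panels)) {
  specs <- panels[[nm]]
  tab <- do.call(rbind, lapply(specs, function(s)
    data.frame(class = s$class_name, speckle_count_mean = s$speckle_count_mean,
               speckle_radius_px = s$speckle_radius_px,
               clustering_strength = s$clustering_strength,
               speckle_intensity = s$speckle_intensity,
               background_level = s$background_level)))
  write.csv(tab, file.path(out, paste0(nm, "_panel.csv")), row.names = FALSE)
  cat(sprintf("panel '%s': %d classes\n", nm, length(specs)))
  print(tab, row.names = FALSE)

  ds <- generate_image_dataset(specs, n_per_class = 3L, size_px = 512L,
                               seed = seeds[[nm]])
  write_image_dataset(ds, file.path(out, nm))
  cat(sprintf("  wrote %d sample image pairs to %s/%s\n\n",
              length(ds$pairs), out, nm))
}
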