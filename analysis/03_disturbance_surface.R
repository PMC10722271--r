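#!/usr/bin/env Rscript
# Stage 3: the anthropogenic disturbance layer - an environmental risk
# surface summing linearly-decaying interference intensities of villages,
# factories, roads, artificial and economic forests.

source("analysis/00_config.R")

land <- build_landscape()
ad <- land$disturbance

v <- ad$values
message(sprintf("disturbance surface: %d cells, intensity 0 .. %.2f",
                length(v), max(v)))
message(sprintf("undisturbed cells (exactly zero): %.1f%%",
                100 * mean(v == 0)))

write_ascii_grid(ad, file.path(scratch_dir, "disturbance.asc"))

by_type <- do.call(rbind, lapply(split(
  land$elements, vapply(land$elements, `[[`, "", "element_type")),
  function(els) {
    s <- build_risk_surface(ad, els)   # per-type partial surface
    data.frame(element_type = els[[1]]$element_type, n = length(els),
               intensity = els[[1]]$intensity,
               max_distance = els[[1]]$max_distance,
               max_cell_value = max(s$values),
               share_of_total = sum(s$values) / sum(v))
  }))
rownames(by_type) <- NULL
write.csv(by_type, file.path(results_dir, "03_disturbance_by_type.csv"),
          row.names = FALSE)
print(by_type)
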