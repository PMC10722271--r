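#!/usr/bin/env Rscript
# Stage 2: plot-level diversity indices - species richness and the
# Shannon-Wiener index (nats) - from the community censuses.

source("analysis/00_config.R")

land <- build_landscape()
div <- compute_diversity_table(land$communities, land$layout)

stopifnot(all(div$shannon <= log(div$richness) + 1e-12))

write.csv(div, file.path(results_dir, "02_plot_diversity.csv"),
          row.names = FALSE)

message(sprintf("richness:  median %d, range %d-%d",
                median(div$richness), min(div$richness), max(div$richness)))
message(sprintf("shannon:   median %.2f, range %.2f-%.2f nats",
                median(div$shannon), min(div$shannon), max(div$shannon)))
message(sprintf("correlation richness ~ shannon: %.2f",
                cor(div$richness, div$shannon)))
message(sprintf("tier medians (richness): coarse %d, fine %d",
                median(div$richness[div$tier == "coarse"]),
                median(div$richness[div$tier == "fine"])))
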