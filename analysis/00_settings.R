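# Shared settings for the analysis scripts. Each numbered script can be run
# on its own from the repository root; stages communicate through the plain
# rasters and tables they write under results/analysis/. The landscape
# itself is regenerated on demand (seeded, so bit-identical every time).

library(ecocircuit)

OUT <- "results/analysis"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

MASTER_SEED <- 11

# study landscape: 180 x 180 cells at the 90 m working grain (16.2 x 16.2 km)
study_spec <- function() landscape_spec(rows = 180, cols = 180, cell_size = 90,
                                        seed = MASTER_SEED)
study_stack <- function() generate_landscape(study_spec())
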