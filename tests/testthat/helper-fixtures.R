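# Shared fixtures built in code.

toy_stack <- function() worked_toy()

# The default toy pipeline run is read by several files; compute it once.
toy_manifest <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(default_pipeline_config(seed = 1))
    cache
  }
})

# Small categorical grid from a literal matrix (row-major for readability).
cat_grid <- function(rows, cell = 30) {
  eco_grid(matrix(unlist(rows), nrow = length(rows), byrow = TRUE),
           cell_size = cell, band_kind = "categorical")
}

# Random multi-class landscape for metric identity checks.
random_landscape <- function(nr = 20, nc = 20, k = 4, cell = 30) {
  eco_grid(matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc),
           cell_size = cell, band_kind = "categorical")
}

# Two-source uniform-resistance strip: sources at the two ends.
two_source_strip <- function(nr = 5, nc = 15, cell = 30, resistance = 1) {
  r <- eco_grid(matrix(resistance, nr, nc), cell_size = cell)
  lab <- matrix(0L, nr, nc); lab[, 1] <- 1L; lab[, nc] <- 1L
  lc <- eco_grid(lab, cell_size = cell, band_kind = "categorical")
  src <- label_patches(lc, foreground = 1, connectivity = 8)
  # relabel: patch 1 = left column, patch 2 = right column (row-major order
  # of first cells already gives left first)
  list(resistance = r, sources = src)
}
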