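# Stage 6: circuit currents and pinch points.
# The resistance lattice becomes a resistor network (conductance = 1 / cost
# kernel); unit current is pushed through every adjacent source pair and the
# summed current map is thresholded inside the corridors to find pinch
# regions.

source("analysis/00_settings.R")

resist <- read_ascii_grid(file.path(OUT, "resistance_integrated.asc"))
srclab <- read_ascii_grid(file.path(OUT, "sources.asc"), "categorical")
corridor <- read_ascii_grid(file.path(OUT, "corridor_mask.asc"), "categorical")
sources <- label_patches(srclab, foreground = setdiff(unique(as.vector(srclab$values)), 0), 8)

net <- cost_network(resist, sources, connectivity = 8)
pairs <- adjacent_pairs(cost_fields(net))
circ <- build_lattice(resist, sources, connectivity = 4)
cm <- cumulative_current(circ, pairs)
pinch <- find_pinch_points(cm$cumulative, corridor, sources, percentile = 0.95)

write_ascii_grid(cm$cumulative, file.path(OUT, "current_cumulative.asc"))
write_ascii_grid(pinch$labels, file.path(OUT, "pinch_regions.asc"))
write.csv(data.frame(pair = names(cm$reff), reff = unname(cm$reff)),
          file.path(OUT, "pair_effective_resistance.csv"), row.names = FALSE)

cat("Solved", nrow(pairs), "source pairs; worst Kirchhoff residual",
    format(cm$max_residual, digits = 3), ".\n")
cat(length(pinch$areas), "pinch regions above the 95th in-corridor current",
    "percentile.\n")
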