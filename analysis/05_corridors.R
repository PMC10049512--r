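# Stage 5: least-cost corridors.
# Cost-weighted distance from every source over the integrated resistance
# surface, cost-allocation adjacency to decide which pairs to link, one
# least-cost path and corridor swath per pair, and the MST key/potential
# split.

source("analysis/00_settings.R")

resist <- read_ascii_grid(file.path(OUT, "resistance_integrated.asc"))
srclab <- read_ascii_grid(file.path(OUT, "sources.asc"), "categorical")
sources <- label_patches(srclab, foreground = setdiff(unique(as.vector(srclab$values)), 0), 8)

net <- cost_network(resist, sources, connectivity = 8)
fields <- cost_fields(net)
pairs <- adjacent_pairs(fields)
cutoff <- 5 * resist$cell_size * mean(resist$values, na.rm = TRUE)
links <- classify_links(build_corridors(net, fields, pairs, cutoff))

corridor <- Reduce(`|`, lapply(links, function(l) l$mask$values != 0))
write_ascii_grid(grid_like(resist, corridor * 1, band_kind = "categorical"),
                 file.path(OUT, "corridor_mask.asc"))
link_table <- data.frame(
  a = vapply(links, function(l) l$pair[1], 0),
  b = vapply(links, function(l) l$pair[2], 0),
  lcd = vapply(links, function(l) l$lcd, 0),
  length_km = vapply(links, function(l) l$length_km, 0),
  klass = vapply(links, function(l) l$klass, ""))
write.csv(link_table, file.path(OUT, "links.csv"), row.names = FALSE)

cat(nrow(link_table), "corridors between", length(sources$areas), "sources:",
    sum(link_table$klass == "key"), "key (MST backbone),",
    sum(link_table$klass == "potential"), "potential;",
    "total length", round(sum(link_table$length_km), 1), "km.\n")
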