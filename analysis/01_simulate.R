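# Stage 1: synthesise the study landscape.
# Writes land cover, DEM and road-distance rasters, and reports the realized
# class composition against the requested mix.

source("analysis/00_settings.R")

spec <- study_spec()
stack <- study_stack()

write_ascii_grid(stack$landcover, file.path(OUT, "landcover.asc"))
write_ascii_grid(stack$dem, file.path(OUT, "dem.asc"))
write_ascii_grid(stack$road1_dist, file.path(OUT, "road1_dist.asc"))
write_ascii_grid(stack$road2_dist, file.path(OUT, "road2_dist.asc"))

cls <- landcover_classes()
frac <- table(factor(stack$landcover$values, levels = cls)) /
  length(stack$landcover$values)
mix <- data.frame(class = names(cls),
                  realized = round(as.numeric(frac), 4))
mix$target <- round(c(1 - sum(spec$class_mix),
                      spec$class_mix[c("forest", "grassland", "shrubland",
                                       "wetland", "water", "artificial",
                                       "bare")]), 4)
write.csv(mix, file.path(OUT, "class_mix.csv"), row.names = FALSE)

cat("Synthesised", spec$rows, "x", spec$cols, "landscape at",
    spec$cell_size, "m; realized class fractions within",
    round(max(abs(mix$realized - mix$target)), 4), "of target.\n")
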