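# Stage 2: habitat quality and ecological sources.
# Degradation from the threat layers, the half-saturation quality index,
# 5-level natural-breaks classification, and extraction of top-level patches
# larger than 2 km^2 as ecological sources.

source("analysis/00_settings.R")

stack <- study_stack()
D <- habitat_degradation(stack)
Q <- habitat_quality(D, stack$landcover)
levels <- classify_quality(Q, 5)
sources <- extract_sources(levels, min_area_km2 = 2)

write_ascii_grid(D, file.path(OUT, "degradation.asc"))
write_ascii_grid(Q, file.path(OUT, "habitat_quality.asc"))
write_ascii_grid(levels, file.path(OUT, "quality_levels.asc"))
write_ascii_grid(sources$labels, file.path(OUT, "sources.asc"))
write.csv(data.frame(source = names(sources$areas),
                     area_km2 = unname(sources$areas)),
          file.path(OUT, "source_areas.csv"), row.names = FALSE)

cat("Mean habitat quality", round(mean(Q$values, na.rm = TRUE), 4),
    "; top-level patches over 2 km^2:", length(sources$areas),
    "(", round(sum(sources$areas), 2), "km^2 total ).\n")
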