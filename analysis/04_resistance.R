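# Stage 4: resistance surfaces.
# Factor grids (land cover, slope, undulation, road distances), the small-
# and large-mammal weighted-sum surfaces, and their cellwise maximum as the
# integrated surface all later stages consume.

source("analysis/00_settings.R")

stack <- study_stack()
factors <- resistance_factors(stack)
tab <- default_resistance_table()
small <- species_resistance(factors, tab, "small")
large <- species_resistance(factors, tab, "large")
integ <- integrated_resistance(small, large)

write_ascii_grid(small, file.path(OUT, "resistance_small.asc"))
write_ascii_grid(large, file.path(OUT, "resistance_large.asc"))
write_ascii_grid(integ, file.path(OUT, "resistance_integrated.asc"))

stats <- data.frame(
  surface = c("small", "large", "integrated"),
  min = c(min(small$values), min(large$values), min(integ$values)),
  max = c(max(small$values), max(large$values), max(integ$values)),
  mean = c(mean(small$values), mean(large$values), mean(integ$values)))
write.csv(stats, file.path(OUT, "resistance_stats.csv"), row.names = FALSE)
print(stats, digits = 4)
cat("Analytic range for the small surface is [1.15, 353.75];",
    "observed extremes must fall inside it.\n")
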