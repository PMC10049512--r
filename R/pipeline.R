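#' Default pipeline configuration
#'
#' Every tunable of the full chain in one list; each default equals the
#' corresponding module-level default. `landscape` may be a
#' `landscape_spec` (synthesised at run time), a ready `landscape_stack`, or
#' `"toy"` for [worked_toy()].
#'
#' @param seed master seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    landscape = "toy",
    threats = default_threats(),
    sensitivity = default_sensitivity(),
    k = 0.5, z = 2.5,
    n_quality_classes = 5,
    min_source_area_km2 = 2.0,
    grains = NULL,                 # NULL = 1..10 x base cell size
    resistance_table = default_resistance_table(),
    undulation_radius = 1,
    cost_connectivity = 8,
    lattice_connectivity = 4,
    corridor_cutoff = NULL,        # NULL = 5 x cell_size x mean resistance
    barrier_diameter_m = 500,
    barrier_stride_cells = NULL,   # NULL = window radius
    barrier_restored_value = NULL, # NULL = resistance-surface minimum
    barrier_top_fraction = 0.10,
    pinch_percentile = 0.95,
    zoning_rules = default_zoning_rules(),
    districts_k = 4,
    out_dir = NULL
  ), class = "pipeline_config")
}

#' Run the full ecological security pattern pipeline
#'
#' Synthesis/ingest, habitat quality, source extraction, grain sweep,
#' resistance surfaces, corridors, circuit currents and pinch points,
#' barrier scan, zoning and reports — in order, with every intermediate
#' kept in the returned manifest (and written to `out_dir` when set).
#' Deterministic under a fixed seed.
#'
#' @param config `pipeline_config`.
#' @return a run manifest: list of parameters, per-stage counts, tables, and
#'   the intermediate objects. `status` is `"ok"` or `"no_sources"`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stack <- if (inherits(config$landscape, "landscape_stack")) config$landscape
    else if (inherits(config$landscape, "landscape_spec")) generate_landscape(config$landscape)
    else if (identical(config$landscape, "toy")) worked_toy()
    else stop("configuration error: unrecognised landscape input")
  cs <- stack$landcover$cell_size

  # habitat quality and sources
  D <- habitat_degradation(stack, config$threats, config$sensitivity)
  Q <- habitat_quality(D, stack$landcover, config$sensitivity,
                       k = config$k, z = config$z)
  levels <- classify_quality(Q, config$n_quality_classes)
  sources <- extract_sources(levels, config$min_source_area_km2)

  # grain sweep (advisory)
  grains <- if (is.null(config$grains)) cs * (1:10) else config$grains
  sweep <- grain_sweep(stack$landcover, grains)
  grain_pick <- select_grain(sweep)

  # resistance surfaces
  factors <- resistance_factors(stack, config$undulation_radius)
  small <- species_resistance(factors, config$resistance_table, "small")
  large <- species_resistance(factors, config$resistance_table, "large")
  resist <- integrated_resistance(small, large)

  manifest <- list(
    status = "ok",
    params = config[setdiff(names(config), c("landscape"))],
    cell_size = cs,
    n_sources = length(sources$areas),
    source_areas_km2 = sources$areas,
    mean_habitat_quality = mean(Q$values, na.rm = TRUE),
    grain_sweep = sweep,
    selected_grain = grain_pick,
    resistance_stats = data.frame(
      surface = c("small", "large", "integrated"),
      min = c(min(small$values, na.rm = TRUE), min(large$values, na.rm = TRUE),
              min(resist$values, na.rm = TRUE)),
      max = c(max(small$values, na.rm = TRUE), max(large$values, na.rm = TRUE),
              max(resist$values, na.rm = TRUE)),
      mean = c(mean(small$values, na.rm = TRUE), mean(large$values, na.rm = TRUE),
               mean(resist$values, na.rm = TRUE))),
    stack = stack, quality = Q, degradation = D, levels = levels,
    sources = sources, resistance = resist
  )
  if (length(sources$areas) < 2) {
    manifest$status <- "no_sources"
    return(manifest)
  }

  # corridors
  net <- cost_network(resist, sources, connectivity = config$cost_connectivity)
  fields <- cost_fields(net)
  pairs <- adjacent_pairs(fields)
  cutoff <- if (is.null(config$corridor_cutoff))
    5 * cs * mean(resist$values, na.rm = TRUE) else config$corridor_cutoff
  links <- classify_links(build_corridors(net, fields, pairs, cutoff))
  corridor_mask <- Reduce(`|`, lapply(links, function(l) l$mask$values != 0))
  key_mask <- Reduce(`|`, c(list(matrix(FALSE, nrow(resist$values), ncol(resist$values))),
    lapply(Filter(function(l) l$klass == "key", links), function(l) l$mask$values != 0)))
  pot_mask <- Reduce(`|`, c(list(matrix(FALSE, nrow(resist$values), ncol(resist$values))),
    lapply(Filter(function(l) l$klass == "potential", links), function(l) l$mask$values != 0)))

  # circuit currents and pinch points
  circ <- build_lattice(resist, sources, connectivity = config$lattice_connectivity)
  cm <- cumulative_current(circ, pairs)
  pinch <- find_pinch_points(cm$cumulative, corridor_mask, sources,
                             percentile = config$pinch_percentile)

  # barriers
  cands <- detect_barriers(net, links, diameter_m = config$barrier_diameter_m,
                           restored_value = config$barrier_restored_value,
                           stride_cells = config$barrier_stride_cells)
  barriers <- barrier_regions(cands, resist, config$barrier_diameter_m,
                              config$barrier_top_fraction)
  is_grid <- is_surface(cands, resist, config$barrier_diameter_m)

  # zoning and reports
  layers <- list(sources = sources, pinch_regions = pinch,
                 key_corridors = grid_like(resist, key_mask * 1, band_kind = "categorical"),
                 potential_corridors = grid_like(resist, pot_mask * 1, band_kind = "categorical"),
                 barrier_regions = barriers, is_grid = is_grid)
  zoning <- apply_zoning(layers, stack$landcover, config$zoning_rules)
  districts <- voronoi_districts(stack$landcover, k = config$districts_k,
                                 seed = config$seed)
  areas <- area_report(zoning$zones, districts)
  counts <- count_report(pinch, barriers, districts)

  manifest <- c(manifest, list(
    n_links = length(links),
    n_key_corridors = sum(vapply(links, function(l) l$klass == "key", TRUE)),
    n_potential_corridors = sum(vapply(links, function(l) l$klass == "potential", TRUE)),
    corridor_cutoff = cutoff,
    links = links,
    link_table = data.frame(
      a = vapply(links, function(l) l$pair[1], 0),
      b = vapply(links, function(l) l$pair[2], 0),
      lcd = vapply(links, function(l) l$lcd, 0),
      length_km = vapply(links, function(l) l$length_km, 0),
      klass = vapply(links, function(l) l$klass, "")),
    current = cm$cumulative,
    pair_reff = cm$reff,
    max_circuit_residual = cm$max_residual,
    n_pinch_regions = length(pinch$areas),
    pinch = pinch,
    barrier_candidates = cands,
    n_barrier_regions = length(barriers$areas),
    barriers = barriers,
    is_grid = is_grid,
    zones = zoning$zones,
    districts = districts,
    area_table = areas,
    count_table = counts
  ))
  if (!is.null(config$out_dir)) write_artifacts(manifest, config$out_dir)
  manifest
}

# Write the pipeline's rasters and tables to a directory.
write_artifacts <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wg <- function(g, nm) if (!is.null(g)) write_ascii_grid(g, file.path(out_dir, paste0(nm, ".asc")))
  wg(manifest$quality, "habitat_quality")
  wg(manifest$degradation, "habitat_degradation")
  wg(manifest$levels, "quality_levels")
  wg(manifest$sources$labels, "sources")
  wg(manifest$resistance, "resistance_integrated")
  wg(manifest$current, "current_cumulative")
  wg(manifest$zones, "zones")
  wg(manifest$districts, "districts")
  wt <- function(df, nm) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  wt(manifest$grain_sweep, "grain_sweep")
  wt(manifest$link_table, "links")
  wt(manifest$area_table, "zone_areas")
  wt(manifest$count_table, "point_counts")
  wt(manifest$barrier_candidates, "barrier_candidates")
  counts <- list(status = manifest$status, n_sources = manifest$n_sources,
                 n_links = manifest$n_links,
                 n_key_corridors = manifest$n_key_corridors,
                 n_pinch_regions = manifest$n_pinch_regions,
                 n_barrier_regions = manifest$n_barrier_regions)
  writeLines(paste(names(counts), unlist(counts), sep = ": "),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
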