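#' Zone codes
#' @return named integer vector: PPZ 1, ERZ 2, SPZ 3, LPZ 4.
#' @export
zone_codes <- function() c(PPZ = 1L, ERZ = 2L, SPZ = 3L, LPZ = 4L)

#' Default four-class protection zoning rules
#'
#' The buffer-and-ingredient rules: the Primary Protected Zone (PPZ) takes
#' the sources plus 1 km around pinch regions and 0.5 km around key
#' corridors; the Eco-Regulation Zone (ERZ) takes 1 km around barrier
#' regions plus high-IS areas, restricted to cultivated and artificial
#' cover; the Secondary Protected Zone (SPZ) takes 0.5 km around potential
#' corridors plus 2 km around sources, restricted to habitat cover; the
#' Living Production Zone (LPZ) is the remainder. Precedence
#' PPZ > ERZ > SPZ > LPZ resolves overlaps.
#'
#' An alternative rule-set keyed on IS bands (SPZ: 0.05 < IS <= 0.15; ERZ:
#' 0 < IS <= 0.05) is available via `variant = "is_bands"`.
#'
#' @param variant `"table"` (ingredient/buffer rules) or `"is_bands"`.
#' @param is_threshold IS cut-off for the high-IS ingredient (table variant).
#' @return a `zoning_rules` list.
#' @export
default_zoning_rules <- function(variant = c("table", "is_bands"),
                                 is_threshold = 0.10) {
  variant <- match.arg(variant)
  cls <- landcover_classes()
  habitat <- unname(cls[c("forest", "grassland", "shrubland", "wetland", "water")])
  human <- unname(cls[c("cultivated", "artificial")])
  structure(list(
    variant = variant,
    is_threshold = is_threshold,
    is_bands = list(SPZ = c(0.05, 0.15), ERZ = c(0, 0.05)),
    zones = list(
      PPZ = list(parts = data.frame(
        ingredient = c("sources", "pinch_regions", "key_corridors"),
        buffer_m = c(0, 1000, 500)), filter = NULL),
      ERZ = list(parts = data.frame(
        ingredient = c("barrier_regions", "high_is_areas"),
        buffer_m = c(1000, 0)), filter = human),
      SPZ = list(parts = data.frame(
        ingredient = c("potential_corridors", "sources"),
        buffer_m = c(500, 2000)), filter = habitat)
    ),
    precedence = c("PPZ", "ERZ", "SPZ", "LPZ")
  ), class = "zoning_rules")
}

# Coerce a layer (patch_set, eco_grid mask, logical matrix, NULL) to logical.
layer_mask <- function(x, tpl) {
  if (is.null(x)) return(matrix(FALSE, nrow(tpl$values), ncol(tpl$values)))
  if (inherits(x, "patch_set")) return(!is.na(x$labels$values) & x$labels$values > 0)
  if (inherits(x, "eco_grid")) return(!is.na(x$values) & x$values != 0)
  x
}

#' Apply the protection zoning rules
#'
#' `layers` must name every ingredient the rules reference:
#' `sources`, `pinch_regions`, `key_corridors`, `potential_corridors`,
#' `barrier_regions` (each a `patch_set`, mask grid, or logical matrix; an
#' all-FALSE mask stands for "none found") and `is_grid` (continuous IS
#' surface, used for the high-IS ingredient and the IS-band variant).
#'
#' @param layers named list of ingredient layers.
#' @param landcover categorical `eco_grid`.
#' @param rules `zoning_rules`.
#' @return list: `zones` (categorical `eco_grid` coded by [zone_codes()])
#'   and `rules`.
#' @export
apply_zoning <- function(layers, landcover, rules = default_zoning_rules()) {
  tpl <- landcover
  cs <- tpl$cell_size
  need <- c("sources", "pinch_regions", "key_corridors",
            "potential_corridors", "barrier_regions", "is_grid")
  miss <- setdiff(need, names(layers))
  if (length(miss))
    stop("configuration error: zoning layer(s) missing: ", paste(miss, collapse = ", "))
  is_vals <- if (is.null(layers$is_grid)) matrix(0, nrow(tpl$values), ncol(tpl$values))
             else layers$is_grid$values
  ingredient_mask <- function(nm) {
    if (nm == "high_is_areas") return(!is.na(is_vals) & is_vals > rules$is_threshold)
    layer_mask(layers[[nm]], tpl)
  }
  zone_mask <- function(zone) {
    zm <- matrix(FALSE, nrow(tpl$values), ncol(tpl$values))
    for (i in seq_len(nrow(zone$parts))) {
      m <- ingredient_mask(zone$parts$ingredient[i])
      bm <- zone$parts$buffer_m[i]
      if (bm > 0 && any(m)) m <- buffer_mask(m, bm, cell_size = cs)
      zm <- zm | m
    }
    if (!is.null(zone$filter)) zm <- zm & (tpl$values %in% zone$filter)
    zm
  }
  masks <- list()
  if (rules$variant == "table") {
    for (zn in names(rules$zones)) masks[[zn]] <- zone_mask(rules$zones[[zn]])
  } else {
    # IS-band variant: PPZ as in the table rules; SPZ/ERZ from IS bands
    masks$PPZ <- zone_mask(rules$zones$PPZ)
    masks$SPZ <- !is.na(is_vals) & is_vals > rules$is_bands$SPZ[1] & is_vals <= rules$is_bands$SPZ[2]
    masks$ERZ <- !is.na(is_vals) & is_vals > rules$is_bands$ERZ[1] & is_vals <= rules$is_bands$ERZ[2]
  }
  zc <- zone_codes()
  zones <- matrix(zc[["LPZ"]], nrow(tpl$values), ncol(tpl$values))
  for (zn in rev(setdiff(rules$precedence, "LPZ"))) {
    if (!is.null(masks[[zn]])) zones[masks[[zn]]] <- zc[[zn]]
  }
  zones[is.na(tpl$values)] <- NA
  list(zones = grid_like(tpl, zones, band_kind = "categorical"), rules = rules)
}

#' Per-district zone area accounting
#'
#' Areas are cell counts times the cell area, so row sums (district totals),
#' column sums (zone totals) and the grand total are exactly consistent by
#' construction.
#'
#' @param zones categorical `eco_grid` from [apply_zoning()].
#' @param districts categorical `eco_grid` of district ids.
#' @return data.frame: one row per district plus a `Total` row; columns PPZ,
#'   ERZ, SPZ, LPZ, Total (km^2).
#' @export
area_report <- function(zones, districts) {
  check_aligned(zones, districts)
  zc <- zone_codes()
  ok <- !is.na(zones$values) & !is.na(districts$values)
  tab <- table(factor(districts$values[ok]),
               factor(zones$values[ok], levels = zc))
  areas <- as.data.frame.matrix(tab) * cell_area_km2(zones)
  names(areas) <- names(zc)
  areas$Total <- rowSums(areas)
  tot <- colSums(areas)
  out <- cbind(district = c(rownames(areas), "Total"),
               rbind(areas, as.data.frame(as.list(tot))))
  rownames(out) <- NULL
  out
}

#' Per-district pinch and barrier region counts
#'
#' Each region is assigned to the district containing its centroid cell; if
#' that cell has no district, the district with the largest overlap wins.
#'
#' @param pinch,barrier `patch_set`s.
#' @param districts categorical `eco_grid`.
#' @return data.frame: district, pinch_points, barrier_points, plus a Total
#'   row.
#' @export
count_report <- function(pinch, barrier, districts) {
  dvals <- districts$values
  dists <- sort(unique(dvals[!is.na(dvals)]))
  count_one <- function(ps) {
    counts <- stats::setNames(integer(length(dists)), dists)
    lab <- ps$labels$values
    for (p in seq_along(ps$areas)) {
      cells <- which(!is.na(lab) & lab == p)
      if (!length(cells)) next
      nr <- nrow(lab)
      rows <- (cells - 1L) %% nr + 1L; cols <- (cells - 1L) %/% nr + 1L
      ctr <- dvals[round(mean(rows)), round(mean(cols))]
      if (is.na(ctr)) {
        ov <- table(dvals[cells])
        if (!length(ov)) next
        ctr <- as.numeric(names(ov)[which.max(ov)])
      }
      counts[as.character(ctr)] <- counts[as.character(ctr)] + 1L
    }
    counts
  }
  pc <- count_one(pinch); bc <- count_one(barrier)
  data.frame(district = c(as.character(dists), "Total"),
             pinch_points = c(unname(pc), sum(pc)),
             barrier_points = c(unname(bc), sum(bc)))
}
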