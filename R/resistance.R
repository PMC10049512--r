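#' Default resistance factor table
#'
#' The five-factor resistance table for the two mammal body-size groups:
#' land cover (weight 0.4) plus slope, surface undulation, and distance to
#' grade-I and grade-II roads (weight 0.15 each). Continuous factors are
#' binned closed-left/open-right; the final bin of each factor closes the
#' domain at infinity. Columns `small` and `large` are the per-bin resistance
#' coefficients of the small-mammal (< 300 g) and large-mammal (> 300 g)
#' groups.
#'
#' @return data.frame with columns `factor`, `weight`, `class`, `bin_low`,
#'   `bin_high`, `small`, `large`.
#' @export
default_resistance_table <- function() {
  lc <- data.frame(
    factor = "landcover", weight = 0.4,
    class = c("cultivated", "forest", "grassland", "shrubland",
              "wetland", "water", "artificial", "bare"),
    bin_low = NA_real_, bin_high = NA_real_,
    small = c(100, 4, 10, 2, 1, 40, 500, 250),
    large = c(65, 4, 20, 1, 2, 20, 600, 200)
  )
  bins <- function(fac, lows, highs, small, large)
    data.frame(factor = fac, weight = 0.15, class = NA_character_,
               bin_low = lows, bin_high = highs, small = small, large = large)
  rbind(
    lc,
    bins("slope", c(0, 8, 15, 25, 35), c(8, 15, 25, 35, Inf),
         c(1, 20, 70, 120, 200), c(1, 10, 50, 75, 120)),
    bins("undulation", c(0, 25, 50, 75, 100), c(25, 50, 75, 100, Inf),
         c(2, 15, 75, 100, 125), c(1, 10, 50, 75, 100)),
    bins("road1", c(0, 200, 400, 800, 1600), c(200, 400, 800, 1600, Inf),
         c(400, 320, 240, 120, 1), c(300, 240, 180, 85, 1)),
    bins("road2", c(0, 150, 350, 750, 1200), c(150, 350, 750, 1200, Inf),
         c(300, 240, 180, 100, 1), c(250, 200, 150, 75, 1))
  )
}

#' Derive the resistance factor grids from a landscape stack
#'
#' Land cover passes through; slope (degrees) comes from the DEM by Horn's
#' method; surface undulation is the focal max-min of the DEM (window
#' half-width `undulation_radius` cells); road distances come from the
#' stack's distance grids.
#'
#' @param stack `landscape_stack`.
#' @param undulation_radius focal window half-width in cells.
#' @return named list of `eco_grid`: landcover, slope, undulation, road1,
#'   road2.
#' @export
resistance_factors <- function(stack, undulation_radius = 1) {
  if (is.null(stack$dem)) stop("configuration error: stack has no DEM")
  list(
    landcover = stack$landcover,
    slope = slope_horn(stack$dem),
    undulation = focal_range(stack$dem, undulation_radius),
    road1 = stack$road1_dist,
    road2 = stack$road2_dist
  )
}

#' Species-group resistance surface
#'
#' Cellwise weighted sum over factors: each cell's value is
#' `sum_f weight_f * coefficient_f(group, bin of cell)`. This is the per-cell
#' surface whose path accumulation the least-cost and circuit stages
#' minimize.
#'
#' @param factors named grids from [resistance_factors()].
#' @param table resistance table as [default_resistance_table()].
#' @param group `"small"` or `"large"`.
#' @return continuous `eco_grid`.
#' @export
species_resistance <- function(factors, table, group = c("small", "large")) {
  group <- match.arg(group)
  cls <- landcover_classes()
  out <- NULL
  for (fac in unique(table$factor)) {
    rows <- table[table$factor == fac, ]
    g <- factors[[fac]]
    if (is.null(g)) stop("configuration error: no factor grid named '", fac, "'")
    v <- g$values
    if (fac == "landcover") {
      coef_by_code <- rep(NA_real_, max(cls))
      coef_by_code[cls[rows$class]] <- rows[[group]]
      r <- matrix(coef_by_code[v], nrow(v), ncol(v))
    } else {
      rows <- rows[order(rows$bin_low), ]
      if (any(v < rows$bin_low[1], na.rm = TRUE))
        stop("data error: factor '", fac, "' has values below its first bin")
      bin <- findInterval(v, rows$bin_low)   # closed-left / open-right
      r <- matrix(rows[[group]][bin], nrow(v), ncol(v))
    }
    contrib <- rows$weight[1] * r
    out <- if (is.null(out)) contrib else out + contrib
  }
  out[is.na(factors$landcover$values)] <- NA
  grid_like(factors$landcover, out, band_kind = "continuous")
}

#' Integrated resistance surface
#'
#' Cellwise maximum of the small- and large-mammal surfaces: each landscape
#' unit takes the larger of the two groups' movement costs, so the
#' integrated surface is conservative for both.
#'
#' @param small,large continuous `eco_grid`s.
#' @return continuous `eco_grid`.
#' @export
integrated_resistance <- function(small, large) {
  check_aligned(small, large)
  grid_like(small, pmax(small$values, large$values), band_kind = "continuous")
}
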