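#' Land-cover class codes
#'
#' The eight land-cover classes used throughout the package, in the fixed
#' coding every categorical land-cover grid is expected to follow.
#'
#' @return named integer vector.
#' @export
landcover_classes <- function() {
  c(cultivated = 1L, forest = 2L, grassland = 3L, shrubland = 4L,
    wetland = 5L, water = 6L, artificial = 7L, bare = 8L)
}

#' Specification of a synthetic landscape
#'
#' Parameters of the seeded generator. `class_mix` gives target fractions for
#' the non-cultivated classes; the remainder is cultivated land. Water and
#' forest cores are guaranteed contiguous patches exceeding
#' `min_core_area_km2` so downstream source extraction always has material to
#' work with.
#'
#' @param rows,cols grid shape.
#' @param cell_size metres per cell edge.
#' @param seed master seed; identical spec + seed gives a bit-identical stack.
#' @param class_mix named fractions for classes other than cultivated;
#'   must lie in [0,1] and sum to <= 1.
#' @param n_water_cores,n_forest_cores number of guaranteed habitat cores.
#' @param min_core_area_km2 minimum area of each core.
#' @param road_grades length-2 integer: number of grade-I and grade-II roads.
#' @param settlement_count number of settlement (artificial surface) seeds.
#' @param relief_amplitude DEM relief in metres.
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(rows = 250, cols = 250, cell_size = 30, seed = 1,
                           class_mix = c(forest = 0.15, grassland = 0.12,
                                         shrubland = 0.05, wetland = 0.04,
                                         water = 0.09, artificial = 0.08,
                                         bare = 0.03),
                           n_water_cores = 2, n_forest_cores = 2,
                           min_core_area_km2 = 2.0,
                           road_grades = c(1, 1),
                           settlement_count = 3,
                           relief_amplitude = 120) {
  if (any(class_mix < 0) || any(class_mix > 1) || sum(class_mix) > 1)
    stop("spec error: class_mix fractions must lie in [0,1] and sum to <= 1")
  structure(list(rows = rows, cols = cols, cell_size = cell_size, seed = seed,
                 class_mix = class_mix, n_water_cores = n_water_cores,
                 n_forest_cores = n_forest_cores,
                 min_core_area_km2 = min_core_area_km2,
                 road_grades = road_grades, settlement_count = settlement_count,
                 relief_amplitude = relief_amplitude),
            class = "landscape_spec")
}

# Separable Gaussian smoothing with replicate padding.
gaussian_smooth <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-h:h, sd = sigma); k <- k / sum(k)
  smooth_lines <- function(mm) {
    nr <- nrow(mm)
    pad <- rbind(mm[rep(1, h), , drop = FALSE], mm, mm[rep(nr, h), , drop = FALSE])
    out <- matrix(0, nr, ncol(mm))
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + nr - 1), , drop = FALSE]
    out
  }
  t(smooth_lines(t(smooth_lines(m))))
}

# Deterministic sub-seeds derived from the master seed, one per layer, so
# adding a feature never perturbs earlier layers.
derive_seeds <- function(seed, n = 8) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic landscape stack
#'
#' Builds an internally consistent input stack on a regular grid: blobby
#' multi-class land cover (thresholded smoothed noise), guaranteed water and
#' forest habitat cores, a smooth DEM, random-walk road polylines of two
#' grades with exact distance grids, and threat masks (settlement = artificial
#' surfaces, mining = bare land, road = union of road cells).
#'
#' @param spec a `landscape_spec`.
#' @return a `landscape_stack`: list with `landcover`, `dem`, `road1_dist`,
#'   `road2_dist`, `road1_mask`, `road2_mask` (all `eco_grid`) and `threats`
#'   (named list of boolean `eco_grid`: settlement, mining, road).
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$rows; nc <- spec$cols; cs <- spec$cell_size
  cls <- landcover_classes()
  cell_km2 <- cs^2 / 1e6
  core_r <- ceiling(sqrt(1.15 * spec$min_core_area_km2 / cell_km2 / pi))
  if (2 * core_r + 4 > min(nr, nc))
    stop("spec error: requested core area does not fit the grid")
  seeds <- derive_seeds(spec$seed)

  # --- guaranteed habitat cores (placed first) ----------------------------
  set.seed(seeds[2])
  n_cores <- spec$n_water_cores + spec$n_forest_cores
  # stratified placement: one core per block of a bn x bn partition, jittered;
  # the core_r + 2 margin inside each block keeps cores disjoint by design
  bn <- ceiling(sqrt(n_cores))
  blk_r <- nr %/% bn; blk_c <- nc %/% bn
  if (min(blk_r, blk_c) < 2 * core_r + 5)
    stop("spec error: could not place ", n_cores, " non-overlapping cores")
  centers <- matrix(0, n_cores, 2)
  for (i in seq_len(n_cores)) {
    bi <- (i - 1) %/% bn; bj <- (i - 1) %% bn
    centers[i, 1] <- sample(seq(bi * blk_r + core_r + 3, (bi + 1) * blk_r - core_r - 2), 1)
    centers[i, 2] <- sample(seq(bj * blk_c + core_r + 3, (bj + 1) * blk_c - core_r - 2), 1)
  }
  core_class <- matrix(0L, nr, nc)
  rr <- row(core_class); cc <- col(core_class)
  for (i in seq_len(n_cores)) {
    disc <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= core_r^2
    core_class[disc] <- if (i <= spec$n_water_cores) cls[["water"]] else cls[["forest"]]
  }

  # --- land cover from smoothed noise -------------------------------------
  set.seed(seeds[1])
  u <- gaussian_smooth(matrix(stats::runif(nr * nc), nr, nc), sigma = max(2, min(nr, nc) / 40))
  # classify the non-core cells; core area counts toward its class's target,
  # so realized whole-map fractions track class_mix
  free <- core_class == 0L
  n_free <- sum(free)
  u_free <- rank(u[free], ties.method = "first") / n_free
  mix <- spec$class_mix
  f_core_w <- sum(core_class == cls[["water"]]) / (nr * nc)
  f_core_f <- sum(core_class == cls[["forest"]]) / (nr * nc)
  adj <- mix
  adj["water"] <- max(0, mix["water"] - f_core_w)
  adj["forest"] <- max(0, mix["forest"] - f_core_f)
  adj <- adj * (nr * nc) / n_free   # rescale targets to the free-cell pool
  # order classes along the moisture/naturalness gradient
  ord <- c("water", "wetland", "forest", "shrubland", "grassland",
           "artificial", "bare")
  lc_free <- rep(cls[["cultivated"]], n_free)
  lo <- 0
  for (nm in ord) {
    frac <- if (nm %in% names(adj)) unname(adj[nm]) else 0
    if (frac > 0) lc_free[u_free > lo & u_free <= lo + frac] <- cls[[nm]]
    lo <- lo + frac
  }
  lc <- core_class
  lc[free] <- lc_free

  # --- DEM -----------------------------------------------------------------
  set.seed(seeds[3])
  dem <- gaussian_smooth(matrix(stats::runif(nr * nc), nr, nc), sigma = max(3, min(nr, nc) / 25))
  dem <- (dem - min(dem)) / (max(dem) - min(dem)) * spec$relief_amplitude + 100

  # --- roads ---------------------------------------------------------------
  road_walk <- function() {
    r <- sample(seq(5, nr - 4), 1)
    m <- matrix(FALSE, nr, nc)
    for (j in seq_len(nc)) {
      m[r, j] <- TRUE
      r <- min(nr, max(1, r + sample(-1:1, 1)))
    }
    m
  }
  set.seed(seeds[4])
  road1 <- matrix(FALSE, nr, nc)
  for (i in seq_len(spec$road_grades[1])) road1 <- road1 | road_walk()
  set.seed(seeds[5])
  road2 <- matrix(FALSE, nr, nc)
  for (i in seq_len(spec$road_grades[2])) road2 <- road2 | road_walk()

  # --- settlements (extra artificial seeds) --------------------------------
  set.seed(seeds[6])
  for (i in seq_len(spec$settlement_count)) {
    r0 <- sample(seq_len(nr - 4), 1); c0 <- sample(seq_len(nc - 4), 1)
    blk_r <- r0:min(nr, r0 + 4); blk_c <- c0:min(nc, c0 + 4)
    sub <- lc[blk_r, blk_c]
    sub[!(sub %in% c(cls[["water"]], cls[["forest"]]))] <- cls[["artificial"]]
    lc[blk_r, blk_c] <- sub
  }

  assemble_stack(lc, dem, road1, road2, cs)
}

# Shared assembly: wraps matrices into grids and derives distances/threats.
assemble_stack <- function(lc, dem, road1, road2, cell_size, origin = c(0, 0)) {
  cls <- landcover_classes()
  g <- function(v, kind) eco_grid(v, cell_size = cell_size, origin = origin, band_kind = kind)
  landcover <- g(lc, "categorical")
  stack <- list(
    landcover = landcover,
    dem = g(dem, "continuous"),
    road1_mask = g(road1 * 1, "categorical"),
    road2_mask = g(road2 * 1, "categorical"),
    road1_dist = g(distance_to(road1, cell_size), "continuous"),
    road2_dist = g(distance_to(road2, cell_size), "continuous"),
    threats = list(
      settlement = g((lc == cls[["artificial"]]) * 1, "categorical"),
      mining = g((lc == cls[["bare"]]) * 1, "categorical"),
      road = g((road1 | road2) * 1, "categorical")
    )
  )
  class(stack) <- "landscape_stack"
  stack
}

#' @exportS3Method base::print
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack: %d x %d cells, cell %g m>\n",
              nrow(x$landcover$values), ncol(x$landcover$values),
              x$landcover$cell_size))
  invisible(x)
}

#' The worked toy landscape
#'
#' A fixed, fully documented 60 x 100 stack (90 m cells) used throughout the
#' test suite and documentation. Two habitat cores — a water body on the west
#' and a forest on the east, each 4.86 km^2 — are separated by a belt of
#' artificial surface with a single grassland neck between rows 25-36. A
#' grade-I road crosses the neck vertically at column 50 and a grade-II road
#' runs along the southern edge. By construction the only low-cost route
#' between the cores runs through the neck (so a corridor and a pinch region
#' must appear there) and the road is the dominant movement barrier on it.
#'
#' @return a `landscape_stack`.
#' @export
worked_toy <- function() {
  nr <- 60L; nc <- 100L; cs <- 90
  cls <- landcover_classes()
  lc <- matrix(cls[["cultivated"]], nr, nc)
  lc[1:24, 26:75] <- cls[["artificial"]]
  lc[37:60, 26:75] <- cls[["artificial"]]
  lc[25:36, 21:80] <- cls[["grassland"]]
  lc[11:50, 6:20] <- cls[["water"]]      # west core: 40 x 15 = 600 cells
  lc[11:50, 81:95] <- cls[["forest"]]    # east core: 40 x 15 = 600 cells
  dem <- 100 + 0.05 * cs * matrix(rep(seq_len(nc), each = nr), nr, nc) / 10
  road1 <- matrix(FALSE, nr, nc); road1[, 50] <- TRUE
  road2 <- matrix(FALSE, nr, nc); road2[58, ] <- TRUE
  assemble_stack(lc, dem, road1, road2, cs)
}

#' Random Voronoi districts
#'
#' Categorical district raster from `k` seeded centres and nearest-centre
#' (Euclidean, ties to the lower centre id) allocation; a stand-in for
#' administrative boundaries in synthetic runs.
#'
#' @param template `eco_grid` supplying shape and georeferencing.
#' @param k number of districts.
#' @param seed RNG seed.
#' @return categorical `eco_grid` with values 1..k.
#' @export
voronoi_districts <- function(template, k = 4, seed = 1) {
  set.seed(as.integer(seed))
  nr <- nrow(template$values); nc <- ncol(template$values)
  ctr <- cbind(sample(seq_len(nr), k, replace = TRUE),
               sample(seq_len(nc), k, replace = TRUE))
  rr <- row(template$values); cc <- col(template$values)
  best <- matrix(1L, nr, nc); bestd <- (rr - ctr[1, 1])^2 + (cc - ctr[1, 2])^2
  for (i in seq_len(k)[-1]) {
    d <- (rr - ctr[i, 1])^2 + (cc - ctr[i, 2])^2
    upd <- d < bestd
    best[upd] <- i; bestd[upd] <- d[upd]
  }
  grid_like(template, best, band_kind = "categorical")
}
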