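#' Label connected patches of a categorical grid
#'
#' Maximal connected components of the foreground classes under rook (4) or
#' queen (8) connectivity. Background and nodata cells are excluded. Labels
#' are consecutive positive integers assigned in row-major order of each
#' patch's first cell, so labelling is deterministic.
#'
#' @param g categorical `eco_grid`.
#' @param foreground vector of class codes treated as foreground.
#' @param connectivity 4 or 8.
#' @return a `patch_set`: list with `labels` (categorical `eco_grid`, 0 =
#'   background), `areas` (named numeric, km^2, sorted by patch id) and
#'   `connectivity`.
#' @export
label_patches <- function(g, foreground, connectivity = 8) {
  stopifnot(inherits(g, "eco_grid"), connectivity %in% c(4, 8))
  fg <- !is.na(g$values) & (g$values %in% foreground)
  lab <- label_mask(fg, connectivity)
  areas <- if (max(lab) > 0) {
    tabulate(lab[lab > 0]) * cell_area_km2(g)
  } else numeric(0)
  names(areas) <- seq_along(areas)
  structure(
    list(labels = grid_like(g, lab, band_kind = "categorical"),
         areas = areas, connectivity = connectivity),
    class = "patch_set"
  )
}

#' @exportS3Method base::print
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set: %d patches, %d-connected, total %.4f km^2>\n",
              length(x$areas), x$connectivity, sum(x$areas)))
  invisible(x)
}

# Connected-component labelling of a logical matrix via igraph components.
# Returns an integer matrix; 0 = background. Patch ids follow row-major order
# of each component's first cell.
label_mask <- function(fg, connectivity = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- matrix(seq_len(nr * nc), nr, nc)   # column-major cell ids
  edges <- lattice_pairs(fg, connectivity)
  lab <- matrix(0L, nr, nc)
  cells <- which(fg)
  if (!length(cells)) return(lab)
  if (nrow(edges)) {
    gph <- igraph::graph_from_edgelist(cbind(match(edges[, 1], cells),
                                             match(edges[, 2], cells)),
                                       directed = FALSE)
    gph <- igraph::add_vertices(gph, max(0L, length(cells) - igraph::vcount(gph)))
    comp <- igraph::components(gph)$membership
  } else {
    comp <- seq_along(cells)
  }
  # relabel so that ids follow row-major order of first occurrence
  rm_order <- order((cells - 1L) %% nr * nc + (cells - 1L) %/% nr)  # row-major rank
  first_seen <- comp[rm_order][!duplicated(comp[rm_order])]
  relab <- integer(max(comp)); relab[first_seen] <- seq_along(first_seen)
  lab[cells] <- relab[comp]
  lab
}

# Edge list (pairs of column-major cell indices) between TRUE cells of a
# logical matrix under 4- or 8-connectivity.
lattice_pairs <- function(fg, connectivity) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  out <- list()
  add <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)
    keep <- fg[a] & fg[b]
    if (any(keep)) out[[length(out) + 1L]] <<- cbind(a[keep], b[keep])
  }
  if (nr > 1) add(idx[-nr, , drop = FALSE], idx[-1, , drop = FALSE])         # down
  if (nc > 1) add(idx[, -nc, drop = FALSE], idx[, -1, drop = FALSE])         # right
  if (connectivity == 8 && nr > 1 && nc > 1) {
    add(idx[-nr, -nc, drop = FALSE], idx[-1, -1, drop = FALSE])              # down-right
    add(idx[-1, -nc, drop = FALSE], idx[-nr, -1, drop = FALSE])              # up-right
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

#' Exact Euclidean distance transform
#'
#' Per-cell Euclidean distance (metres, centre-to-centre) to the nearest
#' `TRUE` cell, computed with the exact two-pass lower-envelope algorithm of
#' Felzenszwalb and Huttenlocher. Cells of an all-`FALSE` mask get `Inf`.
#'
#' @param mask logical matrix or boolean `eco_grid`.
#' @param cell_size metres per cell (taken from the grid when given one).
#' @return numeric matrix of distances in metres (or `eco_grid` when the
#'   input was a grid).
#' @export
distance_to <- function(mask, cell_size = 1) {
  as_grid <- inherits(mask, "eco_grid")
  if (as_grid) { cell_size <- mask$cell_size; tpl <- mask; mask <- !is.na(mask$values) & mask$values != 0 }
  f <- matrix(Inf, nrow(mask), ncol(mask))
  f[mask] <- 0
  # pass 1: columns, pass 2: rows, on squared distances in cell units
  d2 <- apply(f, 2, edt_1d)
  d2 <- t(apply(d2, 1, edt_1d))
  d <- sqrt(d2) * cell_size
  if (as_grid) grid_like(tpl, d, band_kind = "continuous") else d
}

# 1-D squared distance transform (lower envelope of parabolas); Inf entries
# contribute no parabola.
edt_1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(rep(Inf, n))
  m <- length(fin)
  v <- integer(m); z <- numeric(m + 1)
  k <- 1L; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  if (m > 1) for (qi in 2:m) {
    q <- fin[qi]
    repeat {
      p <- v[k]
      s <- ((f[q] + q^2) - (f[p] + p^2)) / (2 * q - 2 * p)
      if (s <= z[k]) {
        k <- k - 1L
      } else {
        k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
        break
      }
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Buffer a boolean mask by Euclidean distance
#'
#' A cell is in the buffer iff its centre lies within `distance_m` (Euclidean,
#' centre-to-centre) of a `TRUE` input cell. Distance 0 returns the input.
#' Monotone: larger distances give supersets.
#'
#' @param mask boolean `eco_grid` (nonzero = TRUE) or logical matrix.
#' @param distance_m buffer distance in metres, >= 0.
#' @param cell_size metres per cell for plain matrices.
#' @return same container type as the input, logical values.
#' @export
buffer_mask <- function(mask, distance_m, cell_size = 1) {
  if (distance_m < 0) stop("distance_m must be >= 0")
  as_grid <- inherits(mask, "eco_grid")
  d <- distance_to(mask, cell_size)
  if (as_grid) {
    grid_like(mask, (d$values <= distance_m) * 1, band_kind = "categorical")
  } else {
    d <= distance_m
  }
}

#' Per-cell range (max - min) over a square moving window
#'
#' The "surface undulation" operator: for each cell, max minus min of the
#' values in the square window of half-width `radius_cells`, ignoring nodata
#' within the window. Cells that are themselves nodata stay nodata.
#'
#' @param g continuous `eco_grid`.
#' @param radius_cells window half-width in cells.
#' @return continuous `eco_grid`.
#' @export
focal_range <- function(g, radius_cells = 1) {
  stopifnot(inherits(g, "eco_grid"), radius_cells >= 0)
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  hi <- matrix(-Inf, nr, nc); lo <- matrix(Inf, nr, nc)
  for (dr in -radius_cells:radius_cells) {
    for (dc in -radius_cells:radius_cells) {
      sh <- shift_mat(v, dr, dc)
      hi <- pmax(hi, sh, na.rm = TRUE)
      lo <- pmin(lo, sh, na.rm = TRUE)
    }
  }
  out <- hi - lo
  out[!is.finite(out)] <- NA
  out[is.na(v)] <- NA
  grid_like(g, out, band_kind = "continuous")
}

# Shift a matrix by (dr, dc), filling exposed cells with NA.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  rs <- seq(max(1, 1 + dr), min(nr, nr + dr))
  cs <- seq(max(1, 1 + dc), min(nc, nc + dc))
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Slope in degrees from a DEM (Horn's 3x3 method)
#'
#' Standard finite-difference slope on a 3x3 neighbourhood with edge rows and
#' columns padded by replication.
#'
#' @param dem continuous `eco_grid` of elevations in metres.
#' @return continuous `eco_grid` of slope in degrees.
#' @export
slope_horn <- function(dem) {
  stopifnot(inherits(dem, "eco_grid"))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  pad <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sub <- function(dr, dc) pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc), drop = FALSE]
  z1 <- sub(0, 0); z2 <- sub(0, 1); z3 <- sub(0, 2)
  z4 <- sub(1, 0);                  z6 <- sub(1, 2)
  z7 <- sub(2, 0); z8 <- sub(2, 1); z9 <- sub(2, 2)
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * dem$cell_size)
  dzdy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * dem$cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(z)] <- NA
  grid_like(dem, slope, band_kind = "continuous")
}

#' Fisher-Jenks natural breaks
#'
#' Optimal 1-D partition of `values` into `n_classes` classes minimizing the
#' total within-class sum of squared deviations, by dynamic programming over
#' the sorted values (deterministic; no heuristics). Returned breaks are the
#' upper bounds of classes 1..n-1; classify with
#' `findInterval(x, breaks) + 1`.
#'
#' @param values numeric vector.
#' @param n_classes number of classes, >= 2.
#' @return numeric vector of `n_classes - 1` interior break values (upper
#'   class bounds, taken at observed values).
#' @export
jenks_breaks <- function(values, n_classes) {
  x <- sort(values[!is.na(values)])
  k <- as.integer(n_classes)
  if (k < 2) stop("n_classes must be >= 2")
  if (length(unique(x)) < k)
    stop("degenerate input: fewer than ", k, " distinct values")
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ssd of x[i..j]
  ssd <- function(i, j) {
    s <- cs[j] - ifelse(i > 1, cs[i - 1], 0)
    s2 <- cs2[j] - ifelse(i > 1, cs2[i - 1], 0)
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)      # D[c, j] = best cost of x[1..j] in c classes
  B <- matrix(0L, k, n)       # split index: last class starts at B[c, j]
  jj <- seq_len(n)
  D[1, ] <- ssd(rep(1L, n), jj)
  B[1, ] <- 1L
  for (c in 2:k) {
    for (j in c:n) {
      i <- c:j                # last class = x[i..j]
      cost <- D[c - 1, i - 1] + ssd(i, rep(j, length(i)))
      best <- which.min(cost)
      D[c, j] <- cost[best]
      B[c, j] <- i[best]
    }
  }
  # backtrack class boundaries
  breaks <- numeric(k - 1)
  j <- n
  for (c in k:2) {
    i <- B[c, j]
    breaks[c - 1] <- x[i - 1]   # upper bound of class c-1
    j <- i - 1L
  }
  breaks
}

#' Classify a numeric vector or grid by Jenks natural breaks
#'
#' For large grids the break optimization runs on a deterministic thinning of
#' the sorted values (every m-th value, capped at `max_n`), then all cells are
#' cut by the resulting breaks.
#'
#' @param g continuous `eco_grid` or numeric vector.
#' @param n_classes number of classes.
#' @param max_n cap on values entering the DP.
#' @return categorical `eco_grid` (or integer vector) of levels 1..n_classes,
#'   n = highest values.
#' @export
jenks_classify <- function(g, n_classes = 5, max_n = 2000) {
  vals <- if (inherits(g, "eco_grid")) as.vector(g$values) else g
  x <- sort(vals[!is.na(vals)])
  if (length(x) > max_n) x <- x[unique(round(seq(1, length(x), length.out = max_n)))]
  breaks <- jenks_breaks(x, n_classes)
  cls <- findInterval(vals, breaks, left.open = TRUE) + 1L
  cls[is.na(vals)] <- NA
  if (inherits(g, "eco_grid")) grid_like(g, matrix(cls, nrow(g$values)), band_kind = "categorical")
  else cls
}
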