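#' Lattice cost network over a resistance surface
#'
#' Shared machinery for the least-cost and barrier stages: the lattice graph
#' whose edge cost between neighbouring cells i, j is
#' `cell_size * geometry_factor * (r_i + r_j) / 2` (geometry factor 1 for
#' rook moves, sqrt(2) for diagonal moves), plus one zero-cost virtual vertex
#' per source patch tied to its member cells so a single Dijkstra run yields
#' the cost-weighted distance (CWD) from a whole patch.
#'
#' @param resistance continuous `eco_grid`, values > 0 on non-nodata cells.
#' @param sources `patch_set` of source patches (may be NULL for a bare
#'   lattice).
#' @param connectivity 4 or 8.
#' @return a `cost_network`: list with the igraph graph, edge table, weights,
#'   template grid, cell count and virtual vertex ids per source.
#' @export
cost_network <- function(resistance, sources = NULL, connectivity = 8) {
  stopifnot(inherits(resistance, "eco_grid"), connectivity %in% c(4, 8))
  r <- resistance$values
  if (any(r <= 0, na.rm = TRUE)) stop("resistance must be > 0 everywhere")
  cs <- resistance$cell_size
  ncell <- length(r)
  ok <- !is.na(r)
  rook <- lattice_pairs_geom(ok, diagonal = FALSE)
  edges <- cbind(rook, geom = rep(1, nrow(rook)))
  if (connectivity == 8) {
    diag <- lattice_pairs_geom(ok, diagonal = TRUE)
    edges <- rbind(edges, cbind(diag, geom = rep(sqrt(2), nrow(diag))))
  }
  w <- cs * edges[, "geom"] * (r[edges[, 1]] + r[edges[, 2]]) / 2
  n_src <- 0L; src_vids <- integer(0)
  if (!is.null(sources)) {
    n_src <- length(sources$areas)
    lab <- sources$labels$values
    for (p in seq_len(n_src)) {
      cells <- which(!is.na(lab) & lab == p)
      vid <- ncell + p
      edges <- rbind(edges, cbind(rep(vid, length(cells)), cells, geom = 0))
      w <- c(w, rep(0, length(cells)))
    }
    src_vids <- ncell + seq_len(n_src)
  }
  g <- igraph::make_empty_graph(n = ncell + n_src, directed = FALSE)
  g <- igraph::add_edges(g, t(edges[, 1:2]))
  structure(list(graph = g, edges = edges, weights = w,
                 template = resistance, ncell = ncell, src_vids = src_vids,
                 connectivity = connectivity),
            class = "cost_network")
}

# Neighbour pairs among TRUE cells: rook or diagonal only.
lattice_pairs_geom <- function(ok, diagonal) {
  nr <- nrow(ok); nc <- ncol(ok)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  out <- list()
  add <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)
    keep <- ok[a] & ok[b]
    if (any(keep)) out[[length(out) + 1L]] <<- cbind(a[keep], b[keep])
  }
  if (!diagonal) {
    if (nr > 1) add(idx[-nr, , drop = FALSE], idx[-1, , drop = FALSE])
    if (nc > 1) add(idx[, -nc, drop = FALSE], idx[, -1, drop = FALSE])
  } else if (nr > 1 && nc > 1) {
    add(idx[-nr, -nc, drop = FALSE], idx[-1, -1, drop = FALSE])
    add(idx[-1, -nc, drop = FALSE], idx[-nr, -1, drop = FALSE])
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

#' Cost-weighted distance from a source cell set
#'
#' Dijkstra over the resistance lattice; CWD is 0 exactly on source cells and
#' `Inf` on unreachable cells.
#'
#' @param resistance continuous `eco_grid` (> 0).
#' @param source_cells integer cell indices (column-major) or a logical
#'   matrix/boolean `eco_grid`.
#' @param connectivity 4 or 8.
#' @return list with `cwd` (continuous `eco_grid`) and `source_cells`.
#' @export
cost_distance <- function(resistance, source_cells, connectivity = 8) {
  if (inherits(source_cells, "eco_grid"))
    source_cells <- which(!is.na(source_cells$values) & source_cells$values != 0)
  if (is.logical(source_cells)) source_cells <- which(source_cells)
  if (!length(source_cells)) stop("source_cells is empty")
  net <- cost_network(resistance, sources = NULL, connectivity = connectivity)
  g <- igraph::add_vertices(net$graph, 1)
  vsrc <- net$ncell + 1L
  g <- igraph::add_edges(g, rbind(rep(vsrc, length(source_cells)), source_cells))
  w <- c(net$weights, rep(0, length(source_cells)))
  d <- as.vector(igraph::distances(g, v = vsrc, weights = w))[seq_len(net$ncell)]
  cwd <- matrix(d, nrow(resistance$values), ncol(resistance$values))
  cwd[is.na(resistance$values)] <- NA
  list(cwd = grid_like(resistance, cwd, band_kind = "continuous"),
       source_cells = source_cells)
}

#' Cost-weighted distance fields for every source patch
#'
#' @param net `cost_network` built with sources.
#' @return list of fields, one per source id: each a list with `source_id`
#'   and `cwd` (`eco_grid`).
#' @export
cost_fields <- function(net) {
  stopifnot(inherits(net, "cost_network"), length(net$src_vids) > 0)
  tpl <- net$template
  lapply(seq_along(net$src_vids), function(p) {
    d <- as.vector(igraph::distances(net$graph, v = net$src_vids[p],
                                     weights = net$weights))[seq_len(net$ncell)]
    cwd <- matrix(d, nrow(tpl$values), ncol(tpl$values))
    cwd[is.na(tpl$values)] <- NA
    list(source_id = p, cwd = grid_like(tpl, cwd, band_kind = "continuous"))
  })
}

#' Cost allocation: CWD-nearest source per cell
#'
#' Ties break to the lower source id, so the allocation is deterministic.
#'
#' @param fields list from [cost_fields()].
#' @return categorical `eco_grid` of source ids.
#' @export
cost_allocation <- function(fields) {
  tpl <- fields[[1]]$cwd
  best <- matrix(1L, nrow(tpl$values), ncol(tpl$values))
  bestd <- fields[[1]]$cwd$values
  for (p in seq_along(fields)[-1]) {
    d <- fields[[p]]$cwd$values
    upd <- !is.na(d) & (is.na(bestd) | d < bestd)   # strict: ties keep lower id
    best[upd] <- p
    bestd[upd] <- d[upd]
  }
  best[is.na(tpl$values)] <- NA
  grid_like(tpl, best, band_kind = "categorical")
}

#' Source pairs whose cost-allocation regions touch
#'
#' The cost-weighted Voronoi adjacency used to build the corridor network:
#' two sources are linked iff their allocation regions share at least one
#' rook lattice edge.
#'
#' @param fields list from [cost_fields()].
#' @return two-column matrix of source-id pairs (a < b), lexicographic order.
#' @export
adjacent_pairs <- function(fields) {
  if (length(fields) < 2) stop("need >= 2 sources")
  alloc <- cost_allocation(fields)$values
  nr <- nrow(alloc); nc <- ncol(alloc)
  prs <- rbind(
    if (nr > 1) cbind(as.vector(alloc[-nr, ]), as.vector(alloc[-1, ])),
    if (nc > 1) cbind(as.vector(alloc[, -nc]), as.vector(alloc[, -1]))
  )
  prs <- prs[stats::complete.cases(prs) & prs[, 1] != prs[, 2], , drop = FALSE]
  prs <- unique(cbind(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2])))
  prs[order(prs[, 1], prs[, 2]), , drop = FALSE]
}

#' Build least-cost corridors for source pairs
#'
#' Per pair: the least-cost distance `LCD = min(CWD_A + CWD_B)`, one optimal
#' path (deterministic Dijkstra between the two source supernodes), the
#' corridor value raster `CWD_A + CWD_B - LCD`, its mask at `<= cutoff`, and
#' the geometric path length.
#'
#' @param net `cost_network` with sources.
#' @param fields list from [cost_fields()].
#' @param pairs two-column matrix of source-id pairs.
#' @param cutoff corridor half-width in cost units (value threshold).
#' @return list of `corridor_link`s: pair, lcd, path (cell indices), value
#'   (`eco_grid`), mask (`eco_grid`), length_km, klass (NA until
#'   [classify_links()]).
#' @export
build_corridors <- function(net, fields, pairs, cutoff) {
  tpl <- net$template
  nr <- nrow(tpl$values)
  links <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    val <- fields[[a]]$cwd$values + fields[[b]]$cwd$values
    lcd <- min(val, na.rm = TRUE)
    if (!is.finite(lcd)) {
      warning("pair (", a, ",", b, ") unreachable; link dropped")
      next
    }
    sp <- igraph::shortest_paths(net$graph, from = net$src_vids[a],
                                 to = net$src_vids[b], weights = net$weights,
                                 output = "vpath")$vpath[[1]]
    cells <- as.integer(sp)
    cells <- cells[cells <= net$ncell]
    rows <- (cells - 1L) %% nr + 1L
    cols <- (cells - 1L) %/% nr + 1L
    steps <- sqrt(diff(rows)^2 + diff(cols)^2)
    corr <- val - lcd
    mask <- !is.na(corr) & corr <= cutoff
    links[[length(links) + 1L]] <- structure(
      list(pair = c(a, b), lcd = lcd, path = cells,
           value = grid_like(tpl, corr, band_kind = "continuous"),
           mask = grid_like(tpl, mask * 1, band_kind = "categorical"),
           length_km = sum(steps) * tpl$cell_size / 1000,
           klass = NA_character_),
      class = "corridor_link")
  }
  links
}

#' @exportS3Method base::print
print.corridor_link <- function(x, ...) {
  cat(sprintf("<corridor %d-%d: LCD %.2f, length %.2f km, %s>\n",
              x$pair[1], x$pair[2], x$lcd, x$length_km,
              ifelse(is.na(x$klass), "unclassified", x$klass)))
  invisible(x)
}

#' Classify corridors as key or potential
#'
#' Links on the minimum spanning tree of the source graph (edge weight =
#' LCD; Kruskal with ties broken by lower LCD then lexicographic pair id)
#' are `key`; the remaining adjacent-pair links are `potential`.
#'
#' @param links list from [build_corridors()].
#' @return the same list with `klass` filled in.
#' @export
classify_links <- function(links) {
  if (!length(links)) return(links)
  lcd <- vapply(links, function(l) l$lcd, 0)
  a <- vapply(links, function(l) l$pair[1], 0)
  b <- vapply(links, function(l) l$pair[2], 0)
  ord <- order(lcd, a, b)
  parent <- seq_len(max(c(a, b)))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  key <- logical(length(links))
  for (i in ord) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) { parent[ra] <- rb; key[i] <- TRUE }
  }
  for (i in seq_along(links)) links[[i]]$klass <- if (key[i]) "key" else "potential"
  links
}

#' Moving-window barrier detection
#'
#' Scans circular windows of diameter `diameter_m` over a band around each
#' corridor. Each window hypothetically restores its cells — resistance is
#' set to `min(current, restored_value)` so restoration can never raise cost
#' — and the link's least-cost distance is recomputed exactly.
#' `delta = LCD_0 - LCD_1` and the improvement score `IS = delta / D`
#' (cost units per metre of window diameter) rank candidate barrier windows.
#'
#' @param net `cost_network` with sources.
#' @param links classified corridor links.
#' @param diameter_m window diameter in metres (>= cell size).
#' @param restored_value resistance assigned inside the window (default: the
#'   minimum of the resistance surface).
#' @param stride_cells centre lattice stride (default: window radius in
#'   cells).
#' @param full_scan scan the whole grid instead of the corridor bands.
#' @return data.frame of candidates sorted by IS descending: row, col, cell,
#'   link_a, link_b, lcd0, lcd1, delta, is.
#' @export
detect_barriers <- function(net, links, diameter_m = 500,
                            restored_value = NULL, stride_cells = NULL,
                            full_scan = FALSE) {
  tpl <- net$template
  cs <- tpl$cell_size
  if (diameter_m < cs) stop("diameter_m must be >= cell size")
  if (is.null(restored_value)) restored_value <- min(tpl$values, na.rm = TRUE)
  if (restored_value <= 0) stop("restored_value must be > 0")
  radius_cells <- diameter_m / 2 / cs
  if (is.null(stride_cells)) stride_cells <- max(1L, floor(radius_cells))
  nr <- nrow(tpl$values); nc <- ncol(tpl$values)
  # disc offsets (centre-to-centre Euclidean radius D/2)
  ro <- -ceiling(radius_cells):ceiling(radius_cells)
  offs <- expand.grid(dr = ro, dc = ro)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_cells^2, ]
  r0 <- tpl$values
  edges <- net$edges
  lattice <- edges[, "geom"] > 0
  out <- list()
  for (l in links) {
    band <- if (full_scan) matrix(TRUE, nr, nc)
            else buffer_mask(l$mask$values != 0 & !is.na(l$mask$values),
                             diameter_m, cell_size = cs)
    centres <- which(band &
                     (row(band) - 1L) %% stride_cells == 0L &
                     (col(band) - 1L) %% stride_cells == 0L)
    va <- net$src_vids[l$pair[1]]; vb <- net$src_vids[l$pair[2]]
    for (ce in centres) {
      crow <- (ce - 1L) %% nr + 1L; ccol <- (ce - 1L) %/% nr + 1L
      wr <- crow + offs$dr; wc <- ccol + offs$dc
      okw <- wr >= 1 & wr <= nr & wc >= 1 & wc <= nc
      wcells <- (wc[okw] - 1L) * nr + wr[okw]
      wcells <- wcells[!is.na(r0[wcells])]
      if (!length(wcells)) next
      rmod <- r0
      rmod[wcells] <- pmin(rmod[wcells], restored_value)
      touched <- logical(nr * nc); touched[wcells] <- TRUE
      sel <- lattice & (touched[edges[, 1]] | touched[edges[, 2]])
      wmod <- net$weights
      wmod[sel] <- cs * edges[sel, "geom"] *
        (rmod[edges[sel, 1]] + rmod[edges[sel, 2]]) / 2
      lcd1 <- igraph::distances(net$graph, v = va, to = vb, weights = wmod)[1, 1]
      out[[length(out) + 1L]] <- data.frame(
        row = crow, col = ccol, cell = ce,
        link_a = l$pair[1], link_b = l$pair[2],
        lcd0 = l$lcd, lcd1 = lcd1, delta = l$lcd - lcd1,
        is = (l$lcd - lcd1) / diameter_m)
    }
  }
  if (!length(out)) return(data.frame())
  cands <- do.call(rbind, out)
  cands[order(-cands$is, cands$cell), ]
}

#' Merge top-scoring barrier windows into regions
#'
#' Takes the top `top_fraction` of candidates by IS (ties at the cut-off
#' value included), unions their windows, and labels 8-connected regions —
#' the "barrier points".
#'
#' @param cands data.frame from [detect_barriers()].
#' @param template `eco_grid` supplying geometry.
#' @param diameter_m window diameter used in the scan.
#' @param top_fraction fraction of candidates kept (default 0.10).
#' @return `patch_set` of barrier regions.
#' @export
barrier_regions <- function(cands, template, diameter_m, top_fraction = 0.10) {
  if (!nrow(cands)) stop("no barrier candidates")
  n_top <- max(1L, ceiling(top_fraction * nrow(cands)))
  cutoff <- sort(cands$is, decreasing = TRUE)[n_top]
  top <- cands[cands$is >= cutoff, ]
  nr <- nrow(template$values); nc <- ncol(template$values)
  cs <- template$cell_size
  radius_cells <- diameter_m / 2 / cs
  ro <- -ceiling(radius_cells):ceiling(radius_cells)
  offs <- expand.grid(dr = ro, dc = ro)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_cells^2, ]
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(top))) {
    wr <- top$row[i] + offs$dr; wc <- top$col[i] + offs$dc
    okw <- wr >= 1 & wr <= nr & wc >= 1 & wc <= nc
    mask[cbind(wr[okw], wc[okw])] <- TRUE
  }
  label_patches(grid_like(template, mask * 1, band_kind = "categorical"),
                foreground = 1, connectivity = 8)
}

#' Rasterized improvement-score surface
#'
#' Per-cell maximum IS over all candidate windows covering the cell; used by
#' the zoning stage's high-IS ingredient.
#'
#' @inheritParams barrier_regions
#' @return continuous `eco_grid` (0 where no window reached the cell).
#' @export
is_surface <- function(cands, template, diameter_m) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  cs <- template$cell_size
  radius_cells <- diameter_m / 2 / cs
  ro <- -ceiling(radius_cells):ceiling(radius_cells)
  offs <- expand.grid(dr = ro, dc = ro)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_cells^2, ]
  m <- matrix(0, nr, nc)
  for (i in seq_len(nrow(cands))) {
    wr <- cands$row[i] + offs$dr; wc <- cands$col[i] + offs$dc
    okw <- wr >= 1 & wr <= nr & wc >= 1 & wc <= nc
    ij <- cbind(wr[okw], wc[okw])
    m[ij] <- pmax(m[ij], cands$is[i])
  }
  m[is.na(template$values)] <- NA
  grid_like(template, m, band_kind = "continuous")
}
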