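#' Solve a resistor network for one terminal pair
#'
#' Core linear solver shared by the lattice stage and usable on any
#' conductance edge list. Injects unit current at node `a`, grounds node
#' `b`, and solves the reduced graph-Laplacian system with a sparse
#' symmetric solve.
#'
#' @param edges two-column matrix of node pairs (1-based).
#' @param g conductances per edge, > 0.
#' @param n number of nodes.
#' @param a,b terminal nodes, a != b.
#' @return list: `potentials` (length n, u[b] = 0), `reff` (effective
#'   resistance), `edge_currents` (signed, along a -> b orientation of each
#'   edge), `node_current` (half the sum of absolute incident edge currents;
#'   terminals fixed at 1), `residual` (max Kirchhoff violation at
#'   non-terminal nodes), `connected` (logical).
#' @export
solve_network <- function(edges, g, n, a, b) {
  stopifnot(a != b, all(g > 0))
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = c(g, g), dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  # connectivity between a and b
  comp <- igraph::components(
    igraph::graph_from_edgelist(edges, directed = FALSE) |>
      (\(gr) igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr))))()
  )$membership
  if (comp[a] != comp[b]) {
    return(list(potentials = rep(NA_real_, n), reff = Inf,
                edge_currents = rep(0, nrow(edges)),
                node_current = rep(0, n), residual = 0, connected = FALSE))
  }
  keep <- setdiff(seq_len(n), b)
  rhs <- numeric(n); rhs[a] <- 1
  u <- numeric(n)
  sol <- Matrix::solve(L[keep, keep, drop = FALSE], rhs[keep])
  u[keep] <- as.vector(sol)
  iedge <- g * (u[edges[, 1]] - u[edges[, 2]])
  node_current <- numeric(n)
  tab <- tapply(abs(iedge), edges[, 1], sum)
  node_current[as.integer(names(tab))] <- tab
  tab <- tapply(abs(iedge), edges[, 2], sum)
  node_current[as.integer(names(tab))] <-
    node_current[as.integer(names(tab))] + tab
  node_current <- node_current / 2
  node_current[c(a, b)] <- 1
  resid <- as.vector(L %*% u) - (rhs - replace(numeric(n), b, 1))
  list(potentials = u, reff = u[a],
       edge_currents = iedge, node_current = node_current,
       residual = max(abs(resid[-c(a, b)]), 0), connected = TRUE)
}

#' Build the circuit lattice over a resistance surface
#'
#' Nodes are non-nodata cells; edge conductance between neighbours is the
#' reciprocal of the movement cost used by [cost_network()],
#' `g = 1 / (cell_size * geometry_factor * (r_i + r_j)/2)`, so the circuit
#' and corridor layers share one cost kernel. Each source patch collapses to
#' a single supernode; parallel conductances sum, internal edges vanish.
#'
#' @param resistance continuous `eco_grid` (> 0).
#' @param sources `patch_set`.
#' @param connectivity 4 (default; keeps the planar current interpretation
#'   clean) or 8.
#' @return a `lattice_circuit`: node map, edge list with conductances,
#'   supernode ids, template.
#' @export
build_lattice <- function(resistance, sources, connectivity = 4) {
  stopifnot(inherits(resistance, "eco_grid"), connectivity %in% c(4, 8))
  r <- resistance$values
  if (any(r <= 0, na.rm = TRUE)) stop("resistance must be > 0")
  cs <- resistance$cell_size
  ok <- !is.na(r)
  lab <- sources$labels$values
  n_src <- length(sources$areas)
  if (n_src > 0 && any(!ok[!is.na(lab) & lab > 0]))
    stop("data error: source patch overlaps nodata cells")
  # node ids: free cells in column-major order, then one node per patch
  nodemap <- matrix(NA_integer_, nrow(r), ncol(r))
  free <- ok & (is.na(lab) | lab == 0)
  nodemap[free] <- seq_len(sum(free))
  n_free <- sum(free)
  for (p in seq_len(n_src)) nodemap[!is.na(lab) & lab == p] <- n_free + p
  n_nodes <- n_free + n_src
  rook <- lattice_pairs_geom(ok, diagonal = FALSE)
  pairs <- cbind(rook, geom = rep(1, nrow(rook)))
  if (connectivity == 8) {
    dg <- lattice_pairs_geom(ok, diagonal = TRUE)
    pairs <- rbind(pairs, cbind(dg, geom = rep(sqrt(2), nrow(dg))))
  }
  gcond <- 1 / (cs * pairs[, "geom"] * (r[pairs[, 1]] + r[pairs[, 2]]) / 2)
  na_ <- nodemap[pairs[, 1]]; nb_ <- nodemap[pairs[, 2]]
  keep <- na_ != nb_
  ekey <- paste(pmin(na_[keep], nb_[keep]), pmax(na_[keep], nb_[keep]))
  agg <- tapply(gcond[keep], ekey, sum)
  ij <- do.call(rbind, strsplit(names(agg), " "))
  edges <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
  structure(list(edges = edges, g = as.numeric(agg), n_nodes = n_nodes,
                 nodemap = nodemap, supernodes = n_free + seq_len(n_src),
                 template = resistance, connectivity = connectivity),
            class = "lattice_circuit")
}

#' Solve one source pair on the lattice
#'
#' Unit current from source `a` to source `b`. The per-cell current is the
#' node current of the cell's node; member cells of the two terminal
#' supernodes carry the injected 1.0.
#'
#' @param circ `lattice_circuit`.
#' @param a,b source ids.
#' @return list: `current` (continuous `eco_grid`), `reff`, `residual`,
#'   `connected`.
#' @export
solve_pair <- function(circ, a, b) {
  stopifnot(a != b)
  sol <- solve_network(circ$edges, circ$g, circ$n_nodes,
                       circ$supernodes[a], circ$supernodes[b])
  cur <- matrix(NA_real_, nrow(circ$nodemap), ncol(circ$nodemap))
  okn <- !is.na(circ$nodemap)
  cur[okn] <- sol$node_current[circ$nodemap[okn]]
  list(current = grid_like(circ$template, cur, band_kind = "continuous"),
       reff = sol$reff, residual = sol$residual, connected = sol$connected)
}

#' Cumulative current over a set of source pairs
#'
#' Sum of per-pair current maps (duplicated pairs are summed twice —
#' deduplication is the caller's job).
#'
#' @param circ `lattice_circuit`.
#' @param pairs two-column matrix of source-id pairs.
#' @return list: `cumulative` (`eco_grid`), `per_pair` (list of solve
#'   results), `reff` (named vector of pair effective resistances),
#'   `max_residual`.
#' @export
cumulative_current <- function(circ, pairs) {
  acc <- NULL
  per <- list(); reffs <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    s <- solve_pair(circ, pairs[i, 1], pairs[i, 2])
    per[[i]] <- s
    reffs[paste0(pairs[i, 1], "-", pairs[i, 2])] <- s$reff
    acc <- if (is.null(acc)) s$current$values else acc + s$current$values
  }
  list(cumulative = grid_like(circ$template, acc, band_kind = "continuous"),
       per_pair = per, reff = reffs,
       max_residual = max(vapply(per, function(x) x$residual, 0)))
}

#' Extract pinch points from a current map
#'
#' Cells inside the corridor mask whose cumulative current reaches the
#' `percentile` quantile of in-mask current, merged into 8-connected
#' regions. Source cells are excluded: their injected current reflects the
#' injection, not a landscape constriction.
#'
#' @param current continuous `eco_grid` (cumulative current).
#' @param corridor_mask boolean `eco_grid` or logical matrix.
#' @param sources `patch_set` (cells excluded) or NULL.
#' @param percentile in-mask current quantile (default 0.95).
#' @return `patch_set` of pinch regions.
#' @export
find_pinch_points <- function(current, corridor_mask, sources = NULL,
                              percentile = 0.95) {
  mask <- if (inherits(corridor_mask, "eco_grid"))
    !is.na(corridor_mask$values) & corridor_mask$values != 0 else corridor_mask
  if (!any(mask)) stop("corridor_mask is empty")
  if (!is.null(sources)) {
    src <- !is.na(sources$labels$values) & sources$labels$values > 0
    mask <- mask & !src
  }
  vals <- current$values[mask]
  vals <- vals[!is.na(vals)]
  thr <- stats::quantile(vals, percentile, names = FALSE)
  hot <- mask & !is.na(current$values) & current$values >= thr
  label_patches(grid_like(current, hot * 1, band_kind = "categorical"),
                foreground = 1, connectivity = 8)
}
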