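# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package implementation.

# Bellman-Ford cost distance over a resistance matrix: repeated relaxation
# until fixpoint. Edge cost = cell * geom * (r_i + r_j) / 2.
bf_cost_oracle <- function(r, cell, source_cells, connectivity = 4) {
  nr <- nrow(r); nc <- ncol(r)
  d <- matrix(Inf, nr, nc)
  d[source_cells] <- 0
  moves <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    moves <- c(moves, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(r[i, j])) next
      for (mv in moves) {
        i2 <- i + mv[1]; j2 <- j + mv[2]
        if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc || is.na(r[i2, j2])) next
        geom <- if (all(mv != 0)) sqrt(2) else 1
        cand <- d[i2, j2] + cell * geom * (r[i, j] + r[i2, j2]) / 2
        if (cand < d[i, j] - 1e-12) { d[i, j] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d
}

# Effective resistance via the dense Laplacian pseudo-inverse.
reff_pinv_oracle <- function(edges, g, n, a, b) {
  L <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    L[i, j] <- L[i, j] - g[e]; L[j, i] <- L[j, i] - g[e]
    L[i, i] <- L[i, i] + g[e]; L[j, j] <- L[j, j] + g[e]
  }
  P <- MASS::ginv(L)
  P[a, a] + P[b, b] - 2 * P[a, b]
}

# Exhaustive Fisher-Jenks: enumerate all contiguous partitions of the sorted
# values into k classes, return the minimal total within-class SSD.
jenks_brute_ssd <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (ci in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, ci], n)
    tot <- sum(vapply(seq_len(k), function(i) ssd(x[(cuts[i] + 1):cuts[i + 1]]), 0))
    if (tot < best) best <- tot
  }
  best
}

# Total within-class SSD achieved by a set of interior breaks.
breaks_ssd <- function(x, breaks) {
  cls <- findInterval(x, breaks, left.open = TRUE) + 1
  sum(vapply(unique(cls), function(cl) {
    v <- x[cls == cl]; sum((v - mean(v))^2)
  }, 0))
}

# Brute-force Euclidean distance transform.
edt_brute <- function(mask, cell = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  if (!nrow(pts)) return(out)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- min(sqrt((pts[, 1] - i)^2 + (pts[, 2] - j)^2)) * cell
  out
}

# Random connected resistor network on n nodes (spanning tree + extra edges).
random_network <- function(n, extra = n) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 0L))
  more <- t(replicate(extra, sample.int(n, 2)))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  edges <- rbind(edges, more)
  g <- stats::runif(nrow(edges), 0.1, 5)
  list(edges = edges, g = g, n = n)
}

# Random small resistance grid (all values > 0).
random_resistance <- function(nr, nc, cell = 30) {
  eco_grid(matrix(stats::runif(nr * nc, 0.5, 20), nr, nc), cell_size = cell)
}
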