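#' Coarsen a categorical grid by majority-rule block aggregation
#'
#' Aggregates `grain / cell_size` blocks of cells to one cell by majority
#' vote; ties break to the smallest class code; trailing partial blocks
#' aggregate over their available cells. Nodata cells are ignored inside a
#' block; an all-nodata block stays nodata.
#'
#' @param landcover categorical `eco_grid`.
#' @param grain target cell size in metres (positive integer multiple of the
#'   base cell size).
#' @return categorical `eco_grid` at the new grain.
#' @export
coarsen_landcover <- function(landcover, grain) {
  f <- grain / landcover$cell_size
  if (f < 1 || abs(f - round(f)) > 1e-9)
    stop("grain must be a positive integer multiple of the base cell size")
  f <- as.integer(round(f))
  v <- landcover$values
  if (f == 1L) return(landcover)
  nr <- nrow(v); nc <- ncol(v)
  nrb <- ceiling(nr / f); ncb <- ceiling(nc / f)
  br <- (row(v) - 1L) %/% f + 1L
  bc <- (col(v) - 1L) %/% f + 1L
  bid <- (bc - 1L) * nrb + br
  ok <- !is.na(v)
  counts <- table(factor(bid[ok], levels = seq_len(nrb * ncb)),
                  factor(v[ok], levels = sort(unique(v[ok]))))
  codes <- as.numeric(colnames(counts))
  out <- rep(NA_real_, nrb * ncb)
  nonzero <- rowSums(counts) > 0
  # which.max returns the first maximum; columns are in ascending code order,
  # so ties resolve to the smallest class code
  out[nonzero] <- codes[apply(counts[nonzero, , drop = FALSE], 1, which.max)]
  eco_grid(matrix(out, nrb, ncb), cell_size = grain, origin = landcover$origin,
           band_kind = "categorical", nodata = landcover$nodata)
}

#' Landscape pattern metrics
#'
#' Standard landscape-level indices, FRAGSTATS conventions: NP (patch count
#' over all classes, 8-connected), DIVISION = 1 - sum (a_i/A)^2, SPLIT =
#' A^2 / sum a_i^2, SHDI = -sum P ln P over class proportions, LSI =
#' 0.25 E / sqrt(A) with E the total edge length including the landscape
#' boundary, and CONTAG from the cell-adjacency entropy (double-count
#' adjacencies; `NA` when fewer than two classes are present).
#'
#' @param landcover categorical `eco_grid`.
#' @return one-row data.frame: grain, NP, DIVISION, LSI, SHDI, CONTAG, SPLIT.
#' @export
landscape_metrics <- function(landcover) {
  v <- landcover$values
  cs <- landcover$cell_size
  cls <- sort(unique(v[!is.na(v)]))
  ncell <- sum(!is.na(v))
  A <- ncell * cs^2
  # patches over all classes
  areas <- numeric(0); np <- 0L
  for (cl in cls) {
    ps <- label_patches(landcover, foreground = cl, connectivity = 8)
    np <- np + length(ps$areas)
    areas <- c(areas, ps$areas * 1e6)  # m^2
  }
  division <- 1 - sum((areas / A)^2)
  split <- A^2 / sum(areas^2)
  p <- as.vector(table(factor(v[!is.na(v)], levels = cls))) / ncell
  shdi <- -sum(p * log(p))
  # edge length: faces between unlike classes (or nodata) + outer boundary
  nr <- nrow(v); nc <- ncol(v)
  vx <- v; vx[is.na(vx)] <- -Inf
  horiz <- if (nc > 1) sum(vx[, -nc] != vx[, -1]) else 0
  vert <- if (nr > 1) sum(vx[-nr, ] != vx[-1, ]) else 0
  edge_faces <- horiz + vert + 2 * (nr + nc)
  lsi <- 0.25 * edge_faces * cs / sqrt(A)
  contag <- contagion_index(v, cls, p)
  data.frame(grain = cs, NP = np, DIVISION = division, LSI = lsi,
             SHDI = shdi, CONTAG = contag, SPLIT = split)
}

# CONTAG from double-counted rook adjacencies; NA for < 2 classes.
contagion_index <- function(v, cls, p) {
  m <- length(cls)
  if (m < 2) return(NA_real_)
  nr <- nrow(v); nc <- ncol(v)
  pairs <- rbind(
    if (nr > 1) cbind(as.vector(v[-nr, ]), as.vector(v[-1, ])),
    if (nc > 1) cbind(as.vector(v[, -nc]), as.vector(v[, -1]))
  )
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  pairs <- rbind(pairs, pairs[, 2:1])  # double count
  g <- table(factor(pairs[, 1], levels = cls), factor(pairs[, 2], levels = cls))
  gsum <- rowSums(g)
  acc <- 0
  for (i in seq_len(m)) {
    if (gsum[i] == 0) next
    for (k in seq_len(m)) {
      q <- p[i] * g[i, k] / gsum[i]
      if (q > 0) acc <- acc + q * log(q)
    }
  }
  100 * (1 + acc / (2 * log(m)))
}

#' Metrics across a granularity sweep
#'
#' Computes [landscape_metrics()] on the landscape coarsened to each grain,
#' the granularity-backstepping table used to choose a working grain.
#'
#' @param landcover categorical `eco_grid` at base resolution.
#' @param grains vector of grains (metres).
#' @return data.frame, one row per grain.
#' @export
grain_sweep <- function(landcover, grains) {
  do.call(rbind, lapply(grains, function(gr) {
    row <- landscape_metrics(coarsen_landcover(landcover, gr))
    row$grain <- gr
    row
  }))
}

#' Select a working grain from the NP-vs-grain curve
#'
#' Returns the grain at the elbow (maximum positive discrete second
#' difference) of the patch-count curve — the point where merging of nearby
#' patches levels off. A featureless (monotone-flat) curve returns the
#' smallest grain with `warning = TRUE`. Advisory only; pipeline buffers and
#' thresholds take their grain from config.
#'
#' @param rows data.frame from [grain_sweep()] (any row order).
#' @return list with `grain` (metres) and `warning` (logical).
#' @export
select_grain <- function(rows) {
  if (nrow(rows) < 3) stop("need >= 3 grain rows")
  rows <- rows[order(rows$grain), ]
  np <- rows$NP
  n <- length(np)
  d2 <- np[1:(n - 2)] - 2 * np[2:(n - 1)] + np[3:n]
  if (all(d2 <= 0) || all(np == np[1]))
    return(list(grain = rows$grain[1], warning = TRUE))
  list(grain = rows$grain[1 + which.max(d2)], warning = FALSE)
}
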