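#' Raster grid data model
#'
#' `eco_grid` is the single carrier for every raster layer in the package: a
#' numeric or integer matrix plus the georeferencing needed to keep layers
#' aligned. Row index increases southward, column index increases eastward
#' (north-up convention); the geographic origin is the upper-left corner of
#' cell (1,1). Nodata cells are stored as `NA` internally; the `nodata`
#' sentinel is only used at file I/O time.
#'
#' @param values numeric matrix (rows = north-to-south).
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, (x, y) of the upper-left corner in
#'   projected metres.
#' @param band_kind `"continuous"` or `"categorical"`.
#' @param nodata sentinel value used when writing to disk.
#' @return an object of class `eco_grid`.
#' @export
eco_grid <- function(values, cell_size = 30, origin = c(0, 0),
                     band_kind = c("continuous", "categorical"),
                     nodata = -9999) {
  band_kind <- match.arg(band_kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid must have >= 1 row and column")
  structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin[1:2]), nodata = nodata,
         band_kind = band_kind),
    class = "eco_grid"
  )
}

#' @exportS3Method base::print
print.eco_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<eco_grid %s: %d x %d, cell %g m, origin (%g, %g)>\n",
              x$band_kind, nrow(x$values), ncol(x$values),
              x$cell_size, x$origin[1], x$origin[2]))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  }
  invisible(x)
}

#' @exportS3Method base::dim
dim.eco_grid <- function(x) dim(x$values)

#' Check that two grids share shape, cell size and origin
#'
#' All cellwise arithmetic between layers requires exact alignment; any
#' mismatch is a hard error rather than a silent resample.
#'
#' @param a,b `eco_grid` objects.
#' @return invisibly `TRUE`; errors on misalignment.
#' @export
check_aligned <- function(a, b) {
  stopifnot(inherits(a, "eco_grid"), inherits(b, "eco_grid"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("alignment error: grid shapes differ (",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), ")")
  if (a$cell_size != b$cell_size)
    stop("alignment error: cell sizes differ (", a$cell_size, " vs ", b$cell_size, ")")
  if (any(a$origin != b$origin))
    stop("alignment error: origins differ")
  invisible(TRUE)
}

#' Derive a grid with new values but identical georeferencing
#' @param g template `eco_grid`.
#' @param values replacement matrix (same shape).
#' @param band_kind optional new band kind.
#' @return `eco_grid`.
#' @export
grid_like <- function(g, values, band_kind = g$band_kind) {
  stopifnot(identical(dim(values), dim(g$values)))
  eco_grid(values, cell_size = g$cell_size, origin = g$origin,
           band_kind = band_kind, nodata = g$nodata)
}

#' Read an ESRI ASCII grid
#'
#' Honours the standard header fields (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) bit-exactly; nodata cells become
#' `NA`. The lower-left corner of the header is converted to this package's
#' upper-left origin convention.
#'
#' @param path file path.
#' @param band_kind band kind to stamp on the result.
#' @return `eco_grid`.
#' @export
read_ascii_grid <- function(path, band_kind = c("continuous", "categorical")) {
  band_kind <- match.arg(band_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  ih <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      ih <- ih + 1L
    } else break
  }
  for (f in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[f]])) stop("format error in ASCII grid header: missing field '", f, "'")
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- paste(lines[(ih + 1L):length(lines)], collapse = " ")
  vals <- scan(text = body, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("format error in ASCII grid: expected ", nr * nc, " values, got ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  eco_grid(m, cell_size = hdr$cellsize, origin = origin,
           band_kind = band_kind, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param g `eco_grid`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_ascii_grid <- function(g, path) {
  stopifnot(inherits(g, "eco_grid"))
  nr <- nrow(g$values); nc <- ncol(g$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %s", formatC(g$origin[1], format = "g", digits = 17)),
    sprintf("yllcorner %s", formatC(g$origin[2] - nr * g$cell_size, format = "g", digits = 17)),
    sprintf("cellsize %s", formatC(g$cell_size, format = "g", digits = 17)),
    sprintf("NODATA_value %s", formatC(g$nodata, format = "g", digits = 17))
  )
  m <- g$values
  m[is.na(m)] <- g$nodata
  rows <- apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a grid file
#'
#' Thin dispatcher kept for pipeline configs that name their format
#' explicitly. Only the text-based ESRI ASCII Grid format is supported.
#'
#' @param path file path.
#' @param format `"ascii_grid"`.
#' @param band_kind band kind.
#' @return `eco_grid`.
#' @export
read_grid <- function(path, format = "ascii_grid",
                      band_kind = c("continuous", "categorical")) {
  format <- match.arg(format, c("ascii_grid"))
  read_ascii_grid(path, band_kind = match.arg(band_kind))
}

#' @rdname read_grid
#' @param g grid to write.
#' @export
write_grid <- function(g, path, format = "ascii_grid") {
  format <- match.arg(format, c("ascii_grid"))
  write_ascii_grid(g, path)
}

#' Area of one cell in km^2
#' @param g `eco_grid`.
#' @return scalar km^2 per cell.
#' @export
cell_area_km2 <- function(g) g$cell_size^2 / 1e6
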