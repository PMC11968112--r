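#' Aligned raster layer stack
#'
#' A `grid_stack` holds named raster layers on a single regular grid. Layers
#' are numeric matrices (row 1 = northernmost row, following the usual raster
#' convention), all sharing the same dimensions, cell size and georeference.
#' Missing cells are `NA`. The coordinate reference system is an opaque
#' identifier that is carried through but never interpreted: all inputs are
#' assumed to share one grid.
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param cell_size Cell edge length in metres (default 500).
#' @param xll,yll Coordinates of the lower-left corner of the grid, metres.
#' @param crs Opaque coordinate-reference identifier, passed through.
#'
#' @return An object of class `grid_stack` with fields `layers`, `n_rows`,
#'   `n_cols`, `cell_size`, `xll`, `yll`, `crs`.
#' @export
#' @examples
#' g <- grid_stack(list(elevation = matrix(1:12, 3, 4)), cell_size = 500)
#' cell_area_km2(g)
grid_stack <- function(layers, cell_size = 500, xll = 0, yll = 0, crs = NA) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty named list of matrices")
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("`layers` must have unique non-empty names")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a positive length in metres")
  structure(
    list(layers = layers, n_rows = dims[1, 1], n_cols = dims[2, 1],
         cell_size = cell_size, xll = xll, yll = yll, crs = crs),
    class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d x %d cells @ %g m, %d layer(s)\n",
              x$n_rows, x$n_cols, x$cell_size, length(x$layers)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[[.grid_stack` <- function(x, name) {
  l <- .subset2(x, "layers")[[name]]
  if (is.null(l) && is.character(name))
    stop(sprintf("layer '%s' not found in grid_stack", name))
  l
}

#' @rdname grid_stack
#' @param x A `grid_stack`.
#' @export
cell_area_km2 <- function(x) {
  stopifnot(inherits(x, "grid_stack"))
  (x$cell_size / 1000)^2
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_stack()].
#' @return A two-column matrix (`x`, `y`) of cell-centre coordinates in grid
#'   units (metres), in column-major cell order (matching `as.vector` of a
#'   layer matrix).
#' @export
cell_centres <- function(grid) {
  stopifnot(inherits(grid, "grid_stack"))
  cs <- grid$cell_size
  # column j -> x; row i (top first) -> y
  xs <- grid$xll + (seq_len(grid$n_cols) - 0.5) * cs
  ys <- grid$yll + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * cs
  cbind(x = rep(xs, each = grid$n_rows), y = rep(ys, times = grid$n_cols))
}

# ---- ESRI ASCII grid I/O (plain-text raster interchange) -------------------

#' Read and write single-layer rasters as ESRI ASCII grids
#'
#' The ASCII grid format (`.asc`) is the plain-text raster interchange format
#' understood by standard GIS tools; it stores the header
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value`)
#' followed by rows of values, north first.
#'
#' @param m Numeric matrix (row 1 = northernmost row).
#' @param path File path.
#' @param cell_size,xll,yll Georeference of the grid.
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a list with `matrix`, `cell_size`, `xll`, `yll`.
#' @export
write_ascii_grid <- function(m, path, cell_size = 500, xll = 0, yll = 0,
                             nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  writeLines(apply(mm, 1L, function(r) paste(format(r, scientific = FALSE,
                                                    trim = TRUE), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- paste(lines[-(1:6)], collapse = " ")
  v <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  stopifnot(length(v) == nc * nr)
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(matrix = m, cell_size = val("cellsize"),
       xll = val("xllcorner"), yll = val("yllcorner"))
}

#' Write every layer of a grid stack as ASCII grids
#'
#' @param grid A [grid_stack()].
#' @param dir Output directory (created if absent); one `<layer>.asc` each.
#' @return Invisibly, the vector of file paths written.
#' @export
write_grid_stack <- function(grid, dir) {
  stopifnot(inherits(grid, "grid_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(grid$layers), function(nm) {
    write_ascii_grid(grid$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                     cell_size = grid$cell_size, xll = grid$xll, yll = grid$yll)
  }, character(1))
  invisible(paths)
}

#' @rdname write_grid_stack
#' @param cell_size,crs Used when reading back (`cell_size` overrides the
#'   header value if non-NULL).
#' @export
read_grid_stack <- function(dir, cell_size = NULL, crs = NA) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0L) stop("no .asc layers found in ", dir)
  reads <- lapply(files, read_ascii_grid)
  layers <- lapply(reads, `[[`, "matrix")
  names(layers) <- sub("\\.asc$", "", basename(files))
  grid_stack(layers,
             cell_size = if (is.null(cell_size)) reads[[1]]$cell_size else cell_size,
             xll = reads[[1]]$xll, yll = reads[[1]]$yll, crs = crs)
}
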