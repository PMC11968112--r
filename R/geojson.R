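# Dissolved unit outlines -> GeoJSON. Each unit's member cells are dissolved
# into rings by chaining the directed boundary edges (interior kept on the
# left, so outer rings come out counter-clockwise and holes clockwise, the
# GeoJSON winding convention).

# Trace closed rings from the set of cells (linear indices into an
# n_rows x n_cols grid). Returns a list of n x 2 coordinate matrices.
trace_unit_rings <- function(cells, n_rows, n_cols, cell_size, xll, yll) {
  inset <- logical(n_rows * n_cols)
  inset[cells] <- TRUE
  idx <- function(i, j) (j - 1L) * n_rows + i
  # vertex key on the (n_rows+1) x (n_cols+1) corner lattice
  vkey <- function(vi, vj) vi * (n_cols + 2L) + vj  # vi in 0..n_rows, vj in 0..n_cols
  edges_from <- list(); efrom <- integer(0); eto <- integer(0)
  for (c0 in cells) {
    i <- ((c0 - 1L) %% n_rows) + 1L
    j <- ((c0 - 1L) %/% n_rows) + 1L
    # corner lattice: (vi, vj) = (i-1, j-1) is the cell's top-left corner
    tl <- c(i - 1L, j - 1L); tr <- c(i - 1L, j); bl <- c(i, j - 1L); br <- c(i, j)
    nb <- function(ii, jj) ii >= 1L && ii <= n_rows && jj >= 1L && jj <= n_cols &&
      inset[idx(ii, jj)]
    add <- function(a, b) {
      efrom <<- c(efrom, vkey(a[1], a[2])); eto <<- c(eto, vkey(b[1], b[2]))
    }
    if (!nb(i + 1L, j)) add(bl, br)        # south side, heading east
    if (!nb(i, j + 1L)) add(br, tr)        # east side, heading north
    if (!nb(i - 1L, j)) add(tr, tl)        # north side, heading west
    if (!nb(i, j - 1L)) add(tl, bl)        # west side, heading south
  }
  if (length(efrom) == 0L) return(list())
  used <- logical(length(efrom))
  out_of <- split(seq_along(efrom), efrom)
  unkey <- function(k) c(k %/% (n_cols + 2L), k %% (n_cols + 2L))
  rings <- list()
  for (start in seq_along(efrom)) {
    if (used[start]) next
    path <- integer(0)
    e <- start
    prev_dir <- NULL
    repeat {
      used[e] <- TRUE
      path <- c(path, e)
      nxt_candidates <- out_of[[as.character(eto[e])]]
      nxt_candidates <- nxt_candidates[!used[nxt_candidates]]
      if (length(nxt_candidates) == 0L) break
      if (length(nxt_candidates) > 1L) {
        # pinch vertex: prefer the sharpest right turn to keep rings simple
        a <- unkey(efrom[e]); b <- unkey(eto[e])
        d_in <- c(b[1] - a[1], b[2] - a[2])
        turn <- vapply(nxt_candidates, function(ne) {
          bb <- unkey(eto[ne])
          d_out <- c(bb[1] - unkey(efrom[ne])[1], bb[2] - unkey(efrom[ne])[2])
          # cross product in (row, col) space; right turn first
          d_in[1] * d_out[2] - d_in[2] * d_out[1]
        }, numeric(1))
        e <- nxt_candidates[order(turn)][1]
      } else e <- nxt_candidates
      if (e == start) break
      if (eto[e] == efrom[path[1]] && used[e]) break
    }
    # vertices: efrom of each edge, closed by repeating the first
    vs <- t(vapply(c(path, path[1]), function(pe) unkey(efrom[pe]), numeric(2)))
    xy <- cbind(x = xll + vs[, 2] * cell_size,
                y = yll + (n_rows - vs[, 1]) * cell_size)
    rings[[length(rings) + 1L]] <- xy
  }
  rings
}

ring_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

point_in_ring <- function(pt, xy) {
  # even-odd rule
  n <- nrow(xy) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((xy[i, 2] > pt[2]) != (xy[j, 2] > pt[2]) &&
        pt[1] < (xy[j, 1] - xy[i, 1]) * (pt[2] - xy[i, 2]) /
          (xy[j, 2] - xy[i, 2]) + xy[i, 1]) inside <- !inside
    j <- i
  }
  inside
}

#' Export unit geometries as GeoJSON
#'
#' Dissolves each unit's member cells into polygon outlines (outer rings
#' counter-clockwise, holes clockwise) and writes a GeoJSON
#' FeatureCollection. Cells with assignment 0 or `NA` ("outside") are
#' skipped.
#'
#' @param assignment Integer matrix of unit ids (0/`NA` = outside).
#' @param grid A [grid_stack()] supplying the georeference.
#' @param properties Optional data frame with a `unit_id` column; its other
#'   columns become feature properties.
#' @param path Output file; when `NULL` the GeoJSON list is returned instead.
#' @return The path (invisibly) or, when `path` is `NULL`, the GeoJSON
#'   structure as a list.
#' @export
units_to_geojson <- function(assignment, grid, properties = NULL, path = NULL) {
  stopifnot(inherits(grid, "grid_stack"),
            all(dim(assignment) == c(grid$n_rows, grid$n_cols)))
  ids <- sort(unique(assignment[!is.na(assignment) & assignment != 0]))
  features <- lapply(ids, function(uid) {
    cells <- which(!is.na(assignment) & assignment == uid)
    rings <- trace_unit_rings(cells, grid$n_rows, grid$n_cols,
                              grid$cell_size, grid$xll, grid$yll)
    areas <- vapply(rings, ring_signed_area, numeric(1))
    outers <- which(areas > 0); holes <- which(areas <= 0)
    polys <- lapply(outers, function(o) list(rings[[o]]))
    if (length(holes) > 0 && length(outers) > 0) {
      for (h in holes) {
        pt <- rings[[h]][1, ] + c(0, 0)  # a lattice vertex of the hole
        # nudge the test point into the hole interior
        pt2 <- colMeans(rings[[h]][-nrow(rings[[h]]), , drop = FALSE])
        owner <- which(vapply(outers, function(o) point_in_ring(pt2, rings[[o]]),
                              logical(1)))[1]
        if (is.na(owner)) owner <- 1L
        polys[[owner]] <- c(polys[[owner]], list(rings[[h]]))
      }
    }
    geom <- if (length(polys) == 1L) {
      list(type = "Polygon", coordinates = polys[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = polys)
    }
    props <- list(unit_id = uid)
    if (!is.null(properties)) {
      row <- properties[properties$unit_id == uid, , drop = FALSE]
      if (nrow(row) == 1L)
        props <- c(props, as.list(row[, setdiff(names(row), "unit_id"),
                                      drop = FALSE]))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  gj <- list(type = "FeatureCollection", features = features)
  if (is.null(path)) return(gj)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
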