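#' Resistance surface raster
#'
#' A georeferenced grid of positive traversal costs with a no-data mask, the
#' substrate for least-cost-path distances. Registration convention used
#' throughout the package: row 1 is the TOP row of the grid and the centre of
#' cell (r, c) sits at
#' `(origin_x + (c - 0.5) * cell_size, origin_y + (n_rows - r + 0.5) * cell_size)`
#' with `(origin_x, origin_y)` the lower-left corner — the ESRI ASCII grid
#' convention.
#'
#' @param values numeric matrix of traversal costs, `NA` = no-data. All
#'   non-missing values must be positive and finite.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin_x,origin_y coordinates of the lower-left grid corner.
#' @return a `resistance_surface` object.
#' @export
resistance_surface <- function(values, cell_size, origin_x = 0, origin_y = 0) {
  values <- as.matrix(values)
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  bad <- which(!is.na(values) & (values <= 0 | !is.finite(values)), arr.ind = TRUE)
  if (length(bad) > 0) {
    stop("non-positive or non-finite cost at cell (", bad[1, 1], ", ", bad[1, 2],
         "); mask no-data cells as NA")
  }
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         cell_size = cell_size, origin_x = origin_x, origin_y = origin_y),
    class = "resistance_surface"
  )
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat("<resistance_surface> ", x$n_rows, "x", x$n_cols, " cells @ ",
      x$cell_size, " m, origin (", x$origin_x, ", ", x$origin_y, "), ",
      sum(is.na(x$values)), " no-data cells\n", sep = "")
  invisible(x)
}

#' Map planar coordinates to raster cells and back
#'
#' @param s a `resistance_surface`.
#' @param x,y coordinate vectors.
#' @return `surface_cell_of()` gives a two-column matrix (row, col) of the
#'   nearest cell (clamped to the grid); `surface_cell_center()` the centre
#'   coordinates of given cells.
#' @keywords internal
surface_cell_of <- function(s, x, y) {
  col <- pmin(pmax(ceiling((x - s$origin_x) / s$cell_size), 1L), s$n_cols)
  row <- pmin(pmax(s$n_rows - ceiling((y - s$origin_y) / s$cell_size) + 1L, 1L), s$n_rows)
  cbind(row = as.integer(row), col = as.integer(col))
}

surface_cell_center <- function(s, row, col) {
  cbind(x = s$origin_x + (col - 0.5) * s$cell_size,
        y = s$origin_y + (s$n_rows - row + 0.5) * s$cell_size)
}

#' Read / write ESRI ASCII grid rasters
#'
#' The six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) is required on read; body rows run from the
#' top of the grid down, matching the in-memory row order. Cost values that
#' are non-positive and not flagged as no-data are rejected.
#'
#' @param path file path.
#' @param s a `resistance_surface` (for writing).
#' @param nodata sentinel written for masked cells.
#' @examples
#' s <- read_resistance(system.file("extdata", "demo_resistance.asc",
#'                                  package = "landgenr"))
#' s
#' @export
read_resistance <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ESRI ASCII header missing: ", paste(miss, collapse = ", "))
  nodata <- hdr[["nodata_value"]]
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) {
    stop("header declares ", hdr$nrows, " rows but body has ", length(body))
  }
  vals <- t(vapply(body, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    if (length(v) != hdr$ncols) {
      stop("row with ", length(v), " values; header declares ", hdr$ncols, " columns")
    }
    v
  }, numeric(hdr$ncols), USE.NAMES = FALSE))
  if (!is.null(nodata)) vals[vals == nodata] <- NA
  resistance_surface(vals, cell_size = hdr$cellsize,
                     origin_x = hdr$xllcorner, origin_y = hdr$yllcorner)
}

#' @rdname read_resistance
#' @export
write_resistance <- function(s, path, nodata = -9999) {
  stopifnot(inherits(s, "resistance_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$n_cols),
    paste("nrows", s$n_rows),
    paste("xllcorner", sprintf("%.17g", s$origin_x)),
    paste("yllcorner", sprintf("%.17g", s$origin_y)),
    paste("cellsize", sprintf("%.17g", s$cell_size)),
    paste("NODATA_value", nodata)
  ), con)
  v <- s$values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Barrier feature set
#'
#' Polylines (roads, non-road linear features) or polygons (forestry
#' cutblocks) in the shared projected coordinate system, used to count
#' barrier crossings along straight lines between individuals.
#'
#' @param features list of two-column coordinate matrices (x, y), one per
#'   feature. Polygon rings need not repeat the first vertex.
#' @param geometry `"polyline"` or `"polygon"`, recycled across features.
#' @param class feature class: `"roads"`, `"cutblocks"` or
#'   `"linear_features"`.
#' @export
barrier_set <- function(features, geometry = "polyline",
                        class = c("roads", "cutblocks", "linear_features")) {
  class <- match.arg(class)
  geometry <- rep_len(geometry, length(features))
  features <- lapply(seq_along(features), function(i) {
    f <- as.matrix(features[[i]])
    if (ncol(f) != 2) stop("feature ", i, " must be a 2-column coordinate matrix")
    if (any(!is.finite(f))) stop("non-finite coordinate in feature ", i)
    minv <- if (geometry[i] == "polygon") 3 else 2
    if (nrow(f) < minv) {
      stop("feature ", i, " has ", nrow(f), " vertices; ", geometry[i],
           " needs at least ", minv)
    }
    f
  })
  structure(list(features = features, geometry = geometry, class = class),
            class = "barrier_set")
}

#' Read barrier features from a GeoJSON FeatureCollection
#'
#' `LineString`, `MultiLineString`, `Polygon` and `MultiPolygon` geometries
#' are accepted; multi-part geometries stay a single feature for counting
#' purposes (a barrier crossed is a feature, however many parts it has), so
#' each part becomes its own entry tagged with a shared feature id.
#'
#' @param path GeoJSON file.
#' @param class barrier class label for the whole set.
#' @examples
#' b <- read_barriers(system.file("extdata", "demo_roads.geojson",
#'                                package = "landgenr"), class = "roads")
#' length(b$features)
#' @export
read_barriers <- function(path, class = c("roads", "cutblocks", "linear_features")) {
  class <- match.arg(class)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- list(); geom <- character(); fid <- integer()
  for (k in seq_along(gj$features)) {
    geo <- gj$features[[k]]$geometry
    coords_of <- function(cc) do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    parts <- switch(geo$type,
      LineString = list(list(cc = coords_of(geo$coordinates), g = "polyline")),
      MultiLineString = lapply(geo$coordinates, function(cc)
        list(cc = coords_of(cc), g = "polyline")),
      Polygon = list(list(cc = coords_of(geo$coordinates[[1]]), g = "polygon")),
      MultiPolygon = lapply(geo$coordinates, function(poly)
        list(cc = coords_of(poly[[1]]), g = "polygon")),
      stop("unsupported geometry type: ", geo$type)
    )
    for (p in parts) {
      cc <- p$cc
      if (p$g == "polygon" && nrow(cc) > 1 &&
          all(cc[1, ] == cc[nrow(cc), ])) cc <- cc[-nrow(cc), , drop = FALSE]
      feats[[length(feats) + 1]] <- cc
      geom <- c(geom, p$g)
      fid <- c(fid, k)
    }
  }
  b <- barrier_set(feats, geometry = geom, class = class)
  b$feature_id <- fid
  b
}
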