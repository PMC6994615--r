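#' Georeferenced raster grid
#'
#' Lightweight raster container used throughout the package. Values are held
#' in a plain matrix whose row 1 is the northernmost row (map north at the
#' top). The origin is the map coordinate of the *outer* corner of pixel
#' (row 1, col 1), i.e. the north-west corner of the grid. Pixels are square,
#' intervals half-open: a point on a shared edge belongs to the pixel with
#' the larger row/column index.
#'
#' @param values numeric (or integer) matrix, row 1 = northernmost row.
#' @param origin length-2 numeric `c(x, y)`: map coordinates of the NW corner.
#' @param pixel_size pixel edge length in meters (> 0).
#' @param band semantic tag, one of `"density"`, `"height_m"`,
#'   `"class_label"`, `"image_band"`, `"gradient"`, `"dem"`, `"label"`.
#' @param nodata sentinel value marking missing pixels (default -9999).
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, nrow(values)), pixel_size = 4,
                        band = "image_band", nodata = -9999) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(values = values, origin = as.numeric(origin),
                 pixel_size = pixel_size, band = band, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- values_masked(x)
  cat(sprintf("<raster_grid> %d x %d px, %.3g m/px, band '%s'\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$band))
  cat(sprintf("  origin (NW): (%.2f, %.2f); range %s\n", x$origin[1],
              x$origin[2],
              if (all(is.na(v))) "all nodata" else
                sprintf("[%.4g, %.4g]", min(v, na.rm = TRUE),
                        max(v, na.rm = TRUE))))
  invisible(x)
}

#' @rdname raster_grid
#' @param x a `raster_grid`.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

## matrix with nodata replaced by NA
values_masked <- function(grid) {
  v <- grid$values
  v[v == grid$nodata] <- NA
  v
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size))
}

#' Map points to pixel indices
#'
#' Half-open pixel convention: a point on a shared edge belongs to the pixel
#' with the larger row/col. Points outside the grid get NA.
#'
#' @param grid a `raster_grid`.
#' @param x,y point map coordinates.
#' @return data.frame with integer columns `row`, `col` (NA when outside).
#' @export
point_to_pixel <- function(grid, x, y) {
  px <- grid$pixel_size
  col <- floor((x - grid$origin[1]) / px) + 1L
  row <- floor((grid$origin[2] - y) / px) + 1L
  ## the very edge of the last row/col still belongs to the grid
  col[x == grid$origin[1] + ncol(grid$values) * px] <- NA_integer_
  row[y == grid$origin[2] - nrow(grid$values) * px] <- NA_integer_
  bad <- is.na(row) | is.na(col) | row < 1L | col < 1L |
    row > nrow(grid$values) | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

pixel_centers <- function(grid) {
  px <- grid$pixel_size
  list(x = grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * px,
       y = grid$origin[2] - (seq_len(nrow(grid$values)) - 0.5) * px)
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text interchange for single-band rasters (`.asc`). The `yllcorner`
#' is derived from the stored NW origin and grid height.
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @export
write_asc <- function(grid, path) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$pixel_size),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  write.table(format(grid$values, scientific = FALSE, trim = TRUE,
                     digits = 15),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @param band semantic band tag to attach on read.
#' @export
read_asc <- function(path, band = "image_band") {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- as.numeric(kv[, 2]); names(h) <- tolower(kv[, 1])
  vals <- as.matrix(read.table(path, skip = 6L))
  dimnames(vals) <- NULL
  raster_grid(vals,
              origin = c(h[["xllcorner"]],
                         h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]]),
              pixel_size = h[["cellsize"]], band = band,
              nodata = h[["nodata_value"]])
}
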