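#' Gridded raster surface
#'
#' A light-weight raster container used throughout the package: a numeric
#' matrix (row 1 = northern edge), a square cell size in metres, and the
#' coordinates of the centre of the top-left cell in an arbitrary local
#' metric frame. `NA` cells are nodata.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param cell_size edge length of a (square) cell in metres; must be > 0.
#' @param origin numeric length-2 `(x, y)` of the top-left cell centre, metres.
#' @return An object of class `sed_raster`.
#' @export
sed_raster <- function(values, cell_size = 5, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2) stop("`origin` must be length 2", call. = FALSE)
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "sed_raster")
}

#' @export
print.sed_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<sed_raster> %d x %d cells @ %g m (%.3g ha)\n",
              nrow(v), ncol(v), x$cell_size,
              sum(!is.na(v)) * x$cell_size^2 / 1e4))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1]))
    cat(sprintf("  values: [%.4g, %.4g], nodata: %d cells\n",
                rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.sed_raster <- function(x) dim(x$values)

#' @export
as.matrix.sed_raster <- function(x, ...) x$values

#' Test two rasters for grid alignment
#'
#' @param a,b `sed_raster` objects.
#' @return `TRUE` if shapes, cell sizes and origins agree.
#' @export
is_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_misaligned <- function(..., what = "rasters") {
  rs <- list(...)
  for (i in seq_along(rs)[-1])
    if (!is_aligned(rs[[1]], rs[[i]]))
      stop(sprintf("misaligned %s (argument %d)", what, i), call. = FALSE)
  invisible(TRUE)
}

#' Cell-centre coordinates of a raster
#'
#' @param r a `sed_raster`.
#' @return list with matrices `x` and `y` (metres) of every cell centre.
#' @export
cell_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  x <- matrix(r$origin[1] + (seq_len(nc) - 1) * r$cell_size, nr, nc, byrow = TRUE)
  y <- matrix(r$origin[2] - (seq_len(nr) - 1) * r$cell_size, nr, nc)
  list(x = x, y = y)
}

#' Area of the non-nodata part of a raster, in hectares
#' @param r a `sed_raster`.
#' @export
raster_area_ha <- function(r) sum(!is.na(r$values)) * r$cell_size^2 / 1e4

#' Read an ESRI ASCII grid
#'
#' Plain-text `.asc` reader (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header followed by row-major values, north first).
#'
#' @param path file path.
#' @return a `sed_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && suppressWarnings(!is.na(as.numeric(parts[2])))) {
      key <- tolower(parts[1])
      if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                     "nodata_value")) {
        hdr[[key]] <- as.numeric(parts[2]); n_hdr <- n_hdr + 1
        next
      }
    }
    break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("missing header field: ", k, call. = FALSE)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body does not match ncols*nrows", call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  # top-left cell centre from lower-left corner
  origin <- c(xll + hdr$cellsize / 2,
              yll + (hdr$nrows - 0.5) * hdr$cellsize)
  sed_raster(m, cell_size = hdr$cellsize, origin = origin)
}

#' Write an ESRI ASCII grid
#'
#' @param r a `sed_raster`.
#' @param path output file path.
#' @param nodata value used to encode `NA` cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.6f", r$origin[1] - r$cell_size / 2),
    sprintf("yllcorner %.6f", r$origin[2] - (nr - 0.5) * r$cell_size),
    sprintf("cellsize %.6f", r$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  v[is.na(v)] <- nodata
  utils::write.table(format(v, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  r_src <- rs - dr; c_src <- cs - dc
  keep_r <- r_src >= 1 & r_src <= nr
  keep_c <- c_src >= 1 & c_src <= nc
  out[rs[keep_r], cs[keep_c]] <- m[r_src[keep_r], c_src[keep_c]]
  out
}

# D8 neighbour table in the fixed tie-break order E, SE, S, SW, W, NW, N, NE.
# dr is the row offset (rows increase southwards), dc the column offset.
d8_offsets <- function() {
  data.frame(code = 1:8,
             name = c("E", "SE", "S", "SW", "W", "NW", "N", "NE"),
             dr = c(0, 1, 1, 1, 0, -1, -1, -1),
             dc = c(1, 1, 0, -1, -1, -1, 0, 1),
             dist = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))
}
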