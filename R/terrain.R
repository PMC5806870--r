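#' Fill depressions in a DEM
#'
#' Raises interior sinks so that every cell has a non-ascending path to the
#' grid edge (or to the nodata boundary). Uses the iterative
#' Planchon-Darboux scheme with a small epsilon gradient so that no flats
#' remain on drained paths.
#'
#' @param dem a `sed_raster` of elevations (m).
#' @param eps minimum per-cell drop imposed while filling (m).
#' @param max_iter safety cap on sweeps.
#' @return a `sed_raster` with depressions filled.
#' @export
fill_depressions <- function(dem, eps = 1e-4, max_iter = 100000L) {
  z <- dem$values
  if (all(is.na(z))) stop("all-nodata DEM", call. = FALSE)
  nr <- nrow(z); nc <- ncol(z)
  valid <- !is.na(z)
  # seed cells drain freely: grid edge or adjacent to nodata
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- TRUE; edge[nr, ] <- TRUE; edge[, 1] <- TRUE; edge[, nc] <- TRUE
  off <- d8_offsets()
  near_na <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off)))
    near_na <- near_na | is.na(shift_mat(z, off$dr[k], off$dc[k], fill = NA))
  seed <- valid & (edge | near_na)

  w <- matrix(Inf, nr, nc)
  w[seed] <- z[seed]
  w[!valid] <- NA
  interior <- valid & !seed
  for (it in seq_len(max_iter)) {
    low <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(off))) {
      cand <- shift_mat(w, off$dr[k], off$dc[k], fill = Inf) + eps * off$dist[k]
      cand[is.na(cand)] <- Inf
      low <- pmin(low, cand)
    }
    new_w <- pmax(z, pmin(w, low))
    new_w[!interior] <- w[!interior]
    done <- all(new_w[interior] == w[interior])
    w <- new_w
    if (done) break
    if (it == max_iter) stop("depression filling did not converge", call. = FALSE)
  }
  if (any(is.infinite(w[valid])))
    stop("isolated cells could not be drained", call. = FALSE)
  sed_raster(w, dem$cell_size, dem$origin)
}

#' D8 flow direction, accumulation and stream network
#'
#' Single steepest-descent direction per cell among its eight neighbours
#' (ties broken in the fixed order E, SE, S, SW, W, NW, N, NE; diagonal
#' drops divided by sqrt(2)*cell). Cells with no lower in-grid neighbour
#' must lie on the grid/nodata boundary, where they drain off-grid
#' (direction code 0); elsewhere they are reported as unresolved flats.
#' Accumulation counts strictly upstream cells (the cell itself excluded);
#' stream cells are those with accumulation >= `threshold`.
#'
#' @param dem a depression-filled `sed_raster`.
#' @param threshold flow-accumulation threshold (upstream cell count)
#'   defining the stream network.
#' @return a `flow_field` list: `direction` (codes 0-8), `accumulation`,
#'   `streams` (logical matrix), `order` (cell indices, upstream first),
#'   `downstream` (flat index of the receiving cell, NA if off-grid),
#'   `outlet` (flat index of the off-grid-draining cell with the largest
#'   accumulation), `cell_size`, `threshold`.
#' @export
d8_flow <- function(dem, threshold = 2000) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  valid <- !is.na(z)
  off <- d8_offsets()
  best_grad <- matrix(-Inf, nr, nc)
  direction <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(off))) {
    # value of the neighbour at (+dr, +dc) seen from each cell
    zn <- shift_mat(z, -off$dr[k], -off$dc[k], fill = NA)
    grad <- (z - zn) / (off$dist[k] * dem$cell_size)
    better <- !is.na(grad) & grad > 0 & grad > best_grad
    best_grad[better] <- grad[better]
    direction[better] <- off$code[k]
  }
  direction[!valid] <- NA_integer_

  # interior cells with no descending neighbour are unresolved flats
  edge <- matrix(FALSE, nr, nc)
  edge[1, ] <- TRUE; edge[nr, ] <- TRUE; edge[, 1] <- TRUE; edge[, nc] <- TRUE
  near_na <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off)))
    near_na <- near_na | is.na(shift_mat(z, off$dr[k], off$dc[k], fill = NA))
  flat <- valid & direction == 0L & !(edge | near_na)
  if (any(flat)) {
    idx <- which(flat)
    stop("unresolvable flat cells after filling at indices: ",
         paste(utils::head(idx, 20), collapse = ", "),
         if (length(idx) > 20) " ..." else "", call. = FALSE)
  }

  # downstream flat index per cell
  dn <- matrix(NA_integer_, nr, nc)
  idx_all <- which(valid & direction > 0L)
  if (length(idx_all)) {
    r0 <- ((idx_all - 1L) %% nr) + 1L
    c0 <- ((idx_all - 1L) %/% nr) + 1L
    k <- direction[idx_all]
    dn[idx_all] <- (c0 + off$dc[k] - 1L) * nr + (r0 + off$dr[k])
  }

  # process cells from high to low; directions always descend strictly
  ord <- which(valid)
  ord <- ord[order(z[ord], decreasing = TRUE)]
  acc <- matrix(NA_real_, nr, nc)
  acc[valid] <- 0
  for (i in ord) {
    j <- dn[i]
    if (!is.na(j)) acc[j] <- acc[j] + acc[i] + 1
  }
  streams <- valid & acc >= threshold
  sinks <- which(valid & direction == 0L)
  outlet <- if (length(sinks)) sinks[which.max(acc[sinks])] else NA_integer_
  structure(list(direction = direction, accumulation = acc, streams = streams,
                 order = ord, downstream = dn, outlet = outlet,
                 cell_size = dem$cell_size, threshold = threshold),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d, %d stream cells (threshold %g)\n",
              nrow(x$direction), ncol(x$direction),
              sum(x$streams, na.rm = TRUE), x$threshold))
  invisible(x)
}

#' Percent slope from a DEM
#'
#' Horn's 8-neighbour third-order finite difference; the grid is edge-padded
#' so border cells effectively use one-sided differences.
#'
#' @param dem a `sed_raster`.
#' @return a `sed_raster` of slope in percent (100 * rise/run).
#' @export
slope_percent <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # pad by replicating edges; nodata cells inherit nearest value for stencil
  zp <- z
  if (anyNA(zp)) {
    # fill nodata with the cell's finite neighbourhood mean for the stencil only
    fill <- mean(zp, na.rm = TRUE)
    zp[is.na(zp)] <- fill
  }
  zp <- rbind(zp[1, , drop = FALSE], zp, zp[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  dzdx <- ((zp[i - 1, j + 1] + 2 * zp[i, j + 1] + zp[i + 1, j + 1]) -
           (zp[i - 1, j - 1] + 2 * zp[i, j - 1] + zp[i + 1, j - 1])) /
          (8 * dem$cell_size)
  dzdy <- ((zp[i + 1, j - 1] + 2 * zp[i + 1, j] + zp[i + 1, j + 1]) -
           (zp[i - 1, j - 1] + 2 * zp[i - 1, j] + zp[i - 1, j + 1])) /
          (8 * dem$cell_size)
  s <- 100 * sqrt(dzdx^2 + dzdy^2)
  s[is.na(z)] <- NA
  sed_raster(s, dem$cell_size, dem$origin)
}

#' Two-dimensional LS factor (Desmet-Govers / McCool)
#'
#' Slope-length factor from upslope contributing area following Desmet &
#' Govers' unit-contributing-area generalization, combined with the McCool
#' piecewise slope-steepness factor. The contributing area at a cell inlet
#' is `accumulation * cell_size^2` (the cell itself excluded).
#'
#' @param flow a `flow_field` (for accumulation and flow direction).
#' @param slope a `sed_raster` of percent slope.
#' @param cell_size cell edge (m); defaults to the flow field's.
#' @param l_max maximum effective slope length (m): contributing area is
#'   capped at `l_max^2`, the conventional bound beyond which overland flow
#'   is assumed to channelize rather than keep lengthening the slope.
#' @return a `sed_raster` of dimensionless LS.
#' @export
ls_factor <- function(flow, slope, cell_size = flow$cell_size, l_max = 122) {
  acc <- flow$accumulation
  if (any(acc < 0, na.rm = TRUE)) stop("negative accumulation", call. = FALSE)
  s <- slope$values
  if (!identical(dim(acc), dim(s)))
    stop("accumulation and slope grids are misaligned", call. = FALSE)
  theta <- atan(s / 100)
  sin_t <- sin(theta)
  beta <- (sin_t / 0.0896) / (3 * sin_t^0.8 + 0.56)
  m <- beta / (1 + beta)
  # aspect factor: 1 for cardinal outflow, sqrt(2) for diagonal, 1 at sinks
  off <- d8_offsets()
  x <- matrix(1, nrow(acc), ncol(acc))
  diag_codes <- off$code[off$dist > 1]
  x[flow$direction %in% diag_codes] <- sqrt(2)
  a_in <- pmin(acc * cell_size^2, l_max^2)
  L <- ((a_in + cell_size^2)^(m + 1) - a_in^(m + 1)) /
       (cell_size^(m + 2) * x^m * 22.13^m)
  S <- ifelse(s < 9, 10.8 * sin_t + 0.03, 16.8 * sin_t - 0.5)
  ls <- L * S
  ls[is.na(acc)] <- NA
  sed_raster(ls, cell_size, slope$origin)
}

#' Euclidean distance to the nearest stream cell
#'
#' Exact distance transform (two-pass lower-envelope algorithm) from cell
#' centres to the nearest stream cell centre, in metres.
#'
#' @param streams logical matrix of stream cells (or a `flow_field`).
#' @param cell_size cell edge in metres.
#' @return a `sed_raster` of distances (0 on stream cells).
#' @export
distance_to_stream <- function(streams, cell_size = 5) {
  if (inherits(streams, "flow_field")) {
    cell_size <- streams$cell_size
    streams <- streams$streams
  }
  if (!any(streams, na.rm = TRUE)) stop("empty stream mask", call. = FALSE)
  st <- streams; st[is.na(st)] <- FALSE
  nr <- nrow(st); nc <- ncol(st)
  # pass 1: squared distance (in cells) to nearest stream within each column
  d2 <- matrix(Inf, nr, nc)
  for (j in seq_len(nc)) {
    rows <- which(st[, j])
    if (!length(rows)) next
    d2[, j] <- (outer(seq_len(nr), rows, "-")^2) |> apply(1, min)
  }
  # pass 2: 1-D lower envelope across columns for each row
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) {
    f <- d2[i, ]
    finite <- which(is.finite(f))
    if (!length(finite)) next
    # lower envelope of parabolas f[q] + (j - q)^2
    v <- integer(nc); zb <- numeric(nc + 1)
    k <- 1L; v[1] <- finite[1]; zb[1] <- -Inf; zb[2] <- Inf
    for (q in finite[-1]) {
      repeat {
        s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
        if (s <= zb[k]) { k <- k - 1L } else break
      }
      k <- k + 1L; v[k] <- q; zb[k] <- s; zb[k + 1] <- Inf
    }
    k <- 1L
    for (j in seq_len(nc)) {
      while (zb[k + 1] < j) k <- k + 1L
      out[i, j] <- (j - v[k])^2 + f[v[k]]
    }
  }
  d <- sqrt(out) * cell_size
  d[is.na(streams)] <- NA
  sed_raster(d, cell_size)
}
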