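#' Mean monthly precipitation climatology for one rain gauge
#'
#' Sums daily precipitation into calendar-month totals for every month in
#' the period, then averages each calendar month over the years observed.
#' Days missing from the record count as zero precipitation (a warning
#' reports how many).
#'
#' @param daily data.frame with columns `date` (Date) and `precip_mm`.
#' @param start,end period limits (Date or parseable strings), inclusive.
#' @return list with `monthly` (length 12, mean total mm for Jan..Dec),
#'   `annual` (sum of the 12 means, mm), `n_missing` (days without record).
#' @export
monthly_climatology <- function(daily, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("empty period", call. = FALSE)
  sel <- daily$date >= start & daily$date <= end
  d <- daily[sel, , drop = FALSE]
  if (any(d$precip_mm < 0, na.rm = TRUE))
    stop("negative precipitation", call. = FALSE)
  all_days <- seq(start, end, by = "day")
  n_missing <- length(all_days) - length(unique(d$date))
  if (n_missing > 0)
    warning(n_missing, " day(s) missing from gauge record; counted as 0 mm",
            call. = FALSE)
  ym <- format(d$date, "%Y-%m")
  totals <- tapply(d$precip_mm, ym, sum)
  # every calendar month in the period contributes, recorded or not
  all_ym <- unique(format(all_days, "%Y-%m"))
  full <- stats::setNames(rep(0, length(all_ym)), all_ym)
  full[names(totals)] <- totals
  mon <- as.integer(substr(names(full), 6, 7))
  monthly <- sapply(1:12, function(m) {
    v <- full[mon == m]
    if (!length(v)) 0 else mean(v)
  })
  list(monthly = monthly, annual = sum(monthly), n_missing = n_missing)
}

#' Cressman interpolation of gauge values onto a grid
#'
#' Single-pass Cressman weighting: for a cell at distance `d < R` from a
#' gauge, the gauge weight is `(R^2 - d^2) / (R^2 + d^2)`; gauges at
#' `d >= R` get weight 0. Cells with no gauge inside the radius fall back
#' to inverse-distance-squared weighting over all gauges (a warning reports
#' how many cells).
#'
#' @param values numeric vector, one value per gauge.
#' @param locations data.frame with gauge coordinates `x`, `y` (m).
#' @param grid a `sed_raster` providing the target geometry.
#' @param radius influence radius R (m), > 0.
#' @return a `sed_raster` of interpolated values.
#' @export
cressman_interpolate <- function(values, locations, grid, radius) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (length(values) != nrow(locations))
    stop("one value per gauge required", call. = FALSE)
  cc <- cell_coords(grid)
  num <- matrix(0, nrow(grid$values), ncol(grid$values))
  den <- num
  idw_num <- num; idw_den <- num
  for (g in seq_along(values)) {
    d2 <- (cc$x - locations$x[g])^2 + (cc$y - locations$y[g])^2
    w <- pmax((radius^2 - d2) / (radius^2 + d2), 0)
    num <- num + w * values[g]
    den <- den + w
    wi <- 1 / pmax(d2, 1e-12)
    idw_num <- idw_num + wi * values[g]
    idw_den <- idw_den + wi
  }
  out <- num / den
  uncovered <- den == 0
  if (any(uncovered & !is.na(grid$values))) {
    warning(sum(uncovered & !is.na(grid$values)),
            " cell(s) outside every gauge radius; inverse-distance fallback",
            call. = FALSE)
    out[uncovered] <- (idw_num / idw_den)[uncovered]
  }
  out[is.na(grid$values)] <- NA
  sed_raster(out, grid$cell_size, grid$origin)
}

#' Rainfall erosivity from monthly precipitation maps
#'
#' Per-cell R factor `R = 68.730 * sum_t (p_t^2 / P)^0.841` over the 12
#' calendar months, with `P` the cell's annual total. Cells with zero
#' annual precipitation get R = 0 with a warning.
#'
#' @param monthly_maps list of 12 aligned `sed_raster`s of mean monthly
#'   precipitation (mm).
#' @return a `sed_raster` of rainfall erosivity (MJ mm ha^-1 h^-1 y^-1).
#' @export
erosivity_map <- function(monthly_maps) {
  if (length(monthly_maps) != 12) stop("need 12 monthly maps", call. = FALSE)
  do.call(stop_if_misaligned, monthly_maps)
  p <- lapply(monthly_maps, function(r) r$values)
  if (any(vapply(p, function(m) any(m < 0, na.rm = TRUE), logical(1))))
    stop("negative monthly precipitation", call. = FALSE)
  p_ann <- Reduce(`+`, p)
  zero <- !is.na(p_ann) & p_ann == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero annual precipitation; R set to 0",
            call. = FALSE)
  p_ann_safe <- ifelse(p_ann > 0, p_ann, 1)
  r <- Reduce(`+`, lapply(p, function(pt) (pt^2 / p_ann_safe)^0.841))
  r <- 68.730 * r
  r[zero] <- 0
  sed_raster(r, monthly_maps[[1]]$cell_size, monthly_maps[[1]]$origin)
}

#' Erosivity raster from multi-gauge daily precipitation
#'
#' Convenience pipeline: per-gauge monthly climatology over the period,
#' Cressman interpolation of each calendar month onto the grid, then
#' [erosivity_map()].
#'
#' @param gauges data.frame with columns `gauge_id`, `x`, `y`, `date`,
#'   `precip_mm`.
#' @param grid target `sed_raster`.
#' @param start,end climatology period (inclusive).
#' @param radius Cressman radius (m); default 1.5 x the maximum
#'   nearest-gauge spacing.
#' @return a `sed_raster` of R.
#' @export
erosivity_from_gauges <- function(gauges, grid, start, end, radius = NULL) {
  ids <- unique(gauges$gauge_id)
  locs <- do.call(rbind, lapply(ids, function(id) {
    g <- gauges[gauges$gauge_id == id, ][1, ]
    data.frame(x = g$x, y = g$y)
  }))
  if (is.null(radius)) {
    if (length(ids) < 2) {
      radius <- max(dim(grid$values)) * grid$cell_size
    } else {
      d <- as.matrix(stats::dist(locs))
      diag(d) <- Inf
      radius <- 1.5 * max(apply(d, 1, min))
    }
  }
  clim <- lapply(ids, function(id)
    monthly_climatology(gauges[gauges$gauge_id == id, c("date", "precip_mm")],
                        start, end))
  monthly_maps <- lapply(1:12, function(m) {
    vals <- vapply(clim, function(cl) cl$monthly[m], numeric(1))
    cressman_interpolate(vals, locs, grid, radius)
  })
  erosivity_map(monthly_maps)
}
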