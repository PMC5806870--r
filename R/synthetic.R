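# simple separable 3x3 box smoothing, `passes` times, edge-replicated
smooth_field <- function(m, passes = 3) {
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    up <- rbind(m[1, , drop = FALSE], m[-nr, , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], m[nr, , drop = FALSE])
    m <- (up + m + dn) / 3
    lf <- cbind(m[, 1, drop = FALSE], m[, -nc, drop = FALSE])
    rt <- cbind(m[, -1, drop = FALSE], m[, nc, drop = FALSE])
    m <- (lf + m + rt) / 3
  }
  m
}

#' Generate a synthetic valley DEM
#'
#' A ridge-to-valley surface: a down-valley tilt (outlet on the southern
#' edge) plus a meandering cross-valley profile whose sides steepen toward
#' the ridges, plus a smoothed Gaussian random field. With
#' `valley_fraction = 0` and `roughness = 0` the result is a plane tilted
#' north-to-south with slope `relief / extent`.
#'
#' @param nx,ny grid size (>= 16 each).
#' @param cell_size cell edge (m).
#' @param relief total relief (m); a fraction `valley_fraction` goes into
#'   the cross-valley ridges, the rest into the down-valley tilt.
#' @param roughness standard deviation (m) of the smoothed random field.
#' @param valley_fraction share of relief in the cross-valley profile.
#' @param seed RNG seed.
#' @return a `sed_raster` DEM.
#' @export
make_dem <- function(nx = 64, ny = 64, cell_size = 5, relief = 80,
                     roughness = 1.5, valley_fraction = 0.75, seed = 1) {
  if (nx < 16 || ny < 16) stop("grid must be at least 16 x 16", call. = FALSE)
  set.seed(seed)
  rowv <- matrix(seq_len(ny), ny, nx)          # 1 = north
  colv <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y_norm <- (ny - rowv) / (ny - 1)             # 0 at south (outlet edge)
  x_norm <- (colv - 1) / (nx - 1)
  down <- (1 - valley_fraction) * relief * y_norm
  xc <- 0.5 + 0.18 * sin(2.5 * pi * y_norm)    # meandering channel axis
  cross <- valley_fraction * relief * abs(x_norm - xc)^1.4
  noise <- if (roughness > 0) {
    f <- smooth_field(matrix(stats::rnorm(ny * nx), ny, nx), passes = 3)
    f * roughness / stats::sd(f)
  } else 0
  sed_raster(down + cross + noise, cell_size)
}

#' Generate a synthetic soil-class map
#'
#' Contiguous patches (nearest-seed-point regions) labelled with the five
#' soil classes of [erodibility_table()]; valley-bottom alluvium (Fluvent,
#' code 5) is forced within two cells of the stream network when one is
#' supplied.
#'
#' @param grid a `sed_raster` providing geometry.
#' @param table erodibility table (defines the class codes).
#' @param seed RNG seed.
#' @param streams optional logical stream mask for the Fluvent rule.
#' @param n_patches number of patch seed points.
#' @return `sed_raster` of soil codes.
#' @export
make_soils <- function(grid, table = erodibility_table(), seed = 1,
                       streams = NULL, n_patches = 12) {
  if (nrow(table) < 1) stop("need at least one soil class", call. = FALSE)
  set.seed(seed + 1000L)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  k <- max(n_patches, nrow(table))
  pr <- stats::runif(k, 1, nr); pc <- stats::runif(k, 1, nc)
  # first seed of each class guarantees presence of all classes
  cls <- c(table$code, sample(table$code, k - nrow(table), replace = TRUE))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best_d <- matrix(Inf, nr, nc); lab <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(k)) {
    d <- (rows - pr[i])^2 + (cols - pc[i])^2
    sel <- d < best_d
    best_d[sel] <- d[sel]; lab[sel] <- cls[i]
  }
  if (!is.null(streams) && any(streams, na.rm = TRUE) &&
      5L %in% table$code) {
    st <- streams; st[is.na(st)] <- FALSE
    near <- st
    for (p in 1:2) {
      grown <- near
      for (k2 in seq_len(nrow(d8_offsets()))) {
        o <- d8_offsets()[k2, ]
        grown <- grown | shift_mat(near * 1, o$dr, o$dc, fill = 0) > 0
      }
      near <- grown
    }
    lab[near] <- 5L
  }
  lab[is.na(grid$values)] <- NA
  sed_raster(lab, grid$cell_size, grid$origin)
}

# mark a sinuous line of cells across the grid; returns flat indices in order
road_path <- function(nr, nc, horizontal = TRUE, at = 0.35, amp = 4,
                      wavelength = 12) {
  if (horizontal) {
    cells <- integer(0)
    prev_r <- NA
    for (j in seq_len(nc)) {
      r <- round(nr * at + amp * sin(j / wavelength))
      r <- min(max(r, 1), nr)
      if (!is.na(prev_r) && abs(r - prev_r) > 1) {
        step <- sign(r - prev_r)
        for (rr in seq(prev_r + step, r - step, by = step))
          cells <- c(cells, (j - 1 - 1) * nr + rr)
      }
      cells <- c(cells, (j - 1) * nr + r)
      prev_r <- r
    }
    cells
  } else {
    cells <- integer(0)
    prev_c <- NA
    for (i in seq_len(nr)) {
      cc <- round(nc * at + amp * sin(i / wavelength))
      cc <- min(max(cc, 1), nc)
      if (!is.na(prev_c) && abs(cc - prev_c) > 1) {
        step <- sign(cc - prev_c)
        for (c2 in seq(prev_c + step, cc - step, by = step))
          cells <- c(cells, (c2 - 1) * nr + i - 1)
      }
      cells <- c(cells, (cc - 1) * nr + i)
      prev_c <- cc
    }
    cells
  }
}

#' Generate a synthetic land-use map
#'
#' Builds the "current" land use of the synthetic watershed: unpaved roads
#' as connected sinuous polylines, micro-dams adjacent to roads, forest on
#' riparian and steep cells, one contiguous eucalyptus stand on mid
#' slopes, and pasture elsewhere. Realized class fractions are within one
#' percentage point of the targets (micro-dams are rounded to whole cells).
#'
#' @param grid geometry `sed_raster`.
#' @param streams logical stream mask.
#' @param slope percent-slope `sed_raster`.
#' @param fractions named percent targets (`pasture` is the remainder).
#' @param seed RNG seed.
#' @param dist optional precomputed distance-to-stream raster.
#' @return `sed_raster` of land-use codes.
#' @export
make_landuse <- function(grid, streams, slope,
                         fractions = c(forest = 25, road = 2,
                                       eucalyptus = 2, microdam = 0.1),
                         seed = 1, dist = NULL) {
  if (sum(fractions) > 100) stop("fractions exceed 100%", call. = FALSE)
  set.seed(seed + 2000L)
  codes <- landuse_codes()
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  n <- sum(!is.na(grid$values))
  lu <- matrix(codes[["pasture"]], nr, nc)
  lu[is.na(grid$values)] <- NA

  target <- function(name) if (name %in% names(fractions))
    round(fractions[[name]] / 100 * n) else 0

  # roads: connected polylines, truncated to the target cell count
  n_road <- target("road")
  if (n_road > 0) {
    cells <- c(road_path(nr, nc, TRUE, at = 0.35),
               road_path(nr, nc, FALSE, at = 0.72),
               road_path(nr, nc, TRUE, at = 0.78))
    cells <- unique(cells[cells >= 1 & cells <= nr * nc])
    cells <- cells[!is.na(lu[cells])]
    lu[cells[seq_len(min(n_road, length(cells)))]] <- codes[["road"]]
  }

  # micro-dams adjacent to roads
  n_dam <- max(target("microdam"), if (target("microdam") > 0) 1L else 0L)
  if (n_dam > 0) {
    road_mask <- lu == codes[["road"]]; road_mask[is.na(road_mask)] <- FALSE
    adj <- matrix(FALSE, nr, nc)
    off <- d8_offsets()
    for (k in seq_len(nrow(off)))
      adj <- adj | shift_mat(road_mask * 1, off$dr[k], off$dc[k], fill = 0) > 0
    cand <- which(adj & lu == codes[["pasture"]])
    pick <- cand[round(seq(1, length(cand), length.out = min(n_dam, length(cand))))]
    lu[pick] <- codes[["microdam"]]
  }

  # forest on riparian + steep cells: highest combined score wins
  n_forest <- target("forest")
  if (n_forest > 0) {
    if (is.null(dist)) dist <- distance_to_stream(streams, grid$cell_size)
    sv <- slope$values
    score <- sv / max(sv, na.rm = TRUE) + 1.5 * exp(-dist$values / 20)
    score[lu != codes[["pasture"]]] <- -Inf
    score[is.na(lu)] <- -Inf
    ord <- order(score, decreasing = TRUE)[seq_len(n_forest)]
    lu[ord] <- codes[["forest"]]
  }

  # eucalyptus: one contiguous stand grown from a mid-slope pasture cell
  n_euc <- target("eucalyptus")
  if (n_euc > 0) {
    pas <- which(lu == codes[["pasture"]])
    sv <- slope$values[pas]
    seed_cell <- pas[which.min(abs(sv - stats::median(sv, na.rm = TRUE)))]
    grown <- integer(0); frontier <- seed_cell
    taken <- rep(FALSE, nr * nc)
    off <- d8_offsets()
    while (length(grown) < n_euc && length(frontier)) {
      cell <- frontier[1]; frontier <- frontier[-1]
      if (taken[cell]) next
      taken[cell] <- TRUE
      if (is.na(lu[cell]) || lu[cell] != codes[["pasture"]]) next
      grown <- c(grown, cell)
      r0 <- ((cell - 1) %% nr) + 1; c0 <- ((cell - 1) %/% nr) + 1
      for (k in seq_len(nrow(off))) {
        rr <- r0 + off$dr[k]; cc <- c0 + off$dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
          frontier <- c(frontier, (cc - 1) * nr + rr)
      }
    }
    lu[grown] <- codes[["eucalyptus"]]
  }
  sed_raster(lu, grid$cell_size, grid$origin)
}

#' Generate synthetic daily rain-gauge records
#'
#' Five gauges spread over the grid, each with seasonal wet-day occurrence
#' and gamma-distributed daily amounts tuned to roughly 1500 mm per year
#' (summer-dominant, as in the humid subtropical highlands the package's
#' synthetic watershed emulates).
#'
#' @param grid geometry `sed_raster`.
#' @param start,end record period (Date or strings).
#' @param n_gauges number of gauges.
#' @param annual_mm target mean annual precipitation.
#' @param seed RNG seed.
#' @return data.frame with `gauge_id`, `x`, `y`, `date`, `precip_mm`.
#' @export
make_rain_gauges <- function(grid, start = "2010-10-01", end = "2015-09-30",
                             n_gauges = 5, annual_mm = 1500, seed = 1) {
  set.seed(seed + 3000L)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ext_x <- (nc - 1) * grid$cell_size; ext_y <- (nr - 1) * grid$cell_size
  fx <- c(0.15, 0.8, 0.5, 0.2, 0.85)[seq_len(n_gauges)]
  fy <- c(0.2, 0.15, 0.55, 0.85, 0.8)[seq_len(n_gauges)]
  days <- seq(as.Date(start), as.Date(end), by = "day")
  doy <- as.integer(format(days, "%j"))
  season <- 0.5 - 0.45 * cos(2 * pi * (doy - 15) / 365.25)  # peaks mid-Jan
  p_wet <- 0.08 + 0.55 * season
  mean_amt <- 2 + 14 * season
  scale_tot <- annual_mm / (365.25 * mean(p_wet * mean_amt))
  out <- lapply(seq_len(n_gauges), function(g) {
    mult <- stats::runif(1, 0.9, 1.1)
    wet <- stats::runif(length(days)) < p_wet
    amt <- ifelse(wet,
                  stats::rgamma(length(days), shape = 0.8,
                                scale = mean_amt * scale_tot * mult / 0.8),
                  0)
    data.frame(gauge_id = sprintf("G%02d", g),
               x = grid$origin[1] + fx[g] * ext_x,
               y = grid$origin[2] - fy[g] * ext_y,
               date = days, precip_mm = amt)
  })
  do.call(rbind, out)
}

#' Generate a synthetic twice-daily outlet gauge series
#'
#' Seasonal baseflow plus storm spikes; turbidity follows the packaged
#' turbidity-discharge curve with optional multiplicative lognormal noise.
#' The discharge series is scaled so that, noise-free, the implied mean
#' sediment export over the period equals `target_se`.
#'
#' @param target_se desired implied mean sediment export (Mg ha^-1 y^-1).
#' @param area_ha drainage area (ha).
#' @param start,end period (Date or strings).
#' @param noise_sd lognormal sigma of the turbidity noise (0 = noise-free).
#' @param seed RNG seed.
#' @return data.frame `timestamp`, `discharge`, `turbidity` with attribute
#'   `implied_se` (the noise-free mean export).
#' @export
make_outlet_series <- function(target_se, area_ha, start = "2010-10-01",
                               end = "2015-09-30", noise_sd = 0.2, seed = 1) {
  set.seed(seed + 4000L)
  stamps <- seq(as.POSIXct(paste(start, "06:00"), tz = "UTC"),
                as.POSIXct(paste(end, "18:00"), tz = "UTC"),
                by = 12 * 3600)
  doy <- as.integer(format(stamps, "%j"))
  season <- 0.5 - 0.45 * cos(2 * pi * (doy - 15) / 365.25)
  base <- 0.08 + 0.18 * season
  storm <- ifelse(stats::runif(length(stamps)) < 0.06 + 0.12 * season,
                  stats::rexp(length(stamps), rate = 1 / 0.5), 0)
  q0 <- base + storm
  implied <- function(s) {
    q <- s * q0
    ss <- suspended_sediment(turbidity_from_discharge(q))
    mean(31.536 * q * ss / area_ha)
  }
  s <- stats::uniroot(function(s) implied(s) - target_se,
                      lower = 1e-4, upper = 200, tol = 1e-10)$root
  q <- s * q0
  tu <- turbidity_from_discharge(q)
  if (noise_sd > 0)
    tu <- tu * stats::rlnorm(length(tu), -noise_sd^2 / 2, noise_sd)
  out <- data.frame(timestamp = stamps, discharge = q, turbidity = tu)
  attr(out, "implied_se") <- implied(s)
  out
}

#' Build a complete synthetic watershed bundle
#'
#' One call generates everything the pipeline needs: DEM (filled), D8 flow
#' field and streams, slope, LS, distance to stream, soil and land-use
#' maps, five rain gauges with an erosivity raster, a "true" parameter set,
#' and a twice-daily outlet series whose implied mean sediment export
#' matches the forward model run under the truth.
#'
#' Two sizes ship: `"mini"` (64 x 64 at 5 m, ~10 ha, stream threshold 100)
#' for fast tests, and `"full"` (693 x 693 at 5 m, ~1200 ha, stream
#' threshold 2000) matching the full problem scale.
#'
#' @param seed RNG seed; the bundle is a deterministic function of it.
#' @param size `"mini"` or `"full"`.
#' @param truth optional named overrides of the true parameter set
#'   (`k_option`, `pasture_c`, `pasture_sre`, `forest_sre`, `linkage`).
#' @param noise_sd turbidity noise for the outlet series.
#' @return list of class `watershed_bundle`.
#' @export
make_reference_watershed <- function(seed = 1, size = c("mini", "full"),
                                     truth = list(), noise_sd = 0.2) {
  size <- match.arg(size)
  nx <- if (size == "mini") 64 else 693
  threshold <- if (size == "mini") 100 else 2000
  relief <- if (size == "mini") 80 else 300
  dem <- make_dem(nx, nx, cell_size = 5, relief = relief, seed = seed)
  filled <- fill_depressions(dem)
  flow <- d8_flow(filled, threshold = threshold)
  slope <- slope_percent(filled)
  ls <- ls_factor(flow, slope)
  dist <- distance_to_stream(flow)
  soilmap <- make_soils(filled, seed = seed, streams = flow$streams)
  landuse <- make_landuse(filled, flow$streams, slope, seed = seed,
                          dist = dist)
  gauges <- make_rain_gauges(filled, seed = seed)
  R <- suppressWarnings(
    erosivity_from_gauges(gauges, filled, "2010-10-01", "2015-09-30"))

  tr <- utils::modifyList(
    list(k_option = "max", pasture_c = 0.135, pasture_sre = 0.05,
         forest_sre = 0.65, linkage = "increasing"), truth)
  bundle <- list(dem = dem, dem_filled = filled, flow = flow, slope = slope,
                 ls = ls, dist = dist, soilmap = soilmap, landuse = landuse,
                 gauges = gauges, R = R, seed = seed, size = size)
  params <- resolve_member_params(tr$pasture_c, tr$pasture_sre,
                                  tr$forest_sre, tr$linkage)
  truth_run <- run_erosion_model(bundle, params, tr$k_option)
  tr$observed_se <- truth_run$outlet_export
  tr$mean_soil_loss <- truth_run$mean_soil_loss
  bundle$outlet_series <- make_outlet_series(tr$observed_se,
                                             truth_run$area_ha,
                                             noise_sd = noise_sd, seed = seed)
  tr$gauge_implied_se <- attr(bundle$outlet_series, "implied_se")
  bundle$truth <- tr
  bundle$area_ha <- truth_run$area_ha
  structure(bundle, class = "watershed_bundle")
}

#' @export
print.watershed_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<watershed_bundle> %s, seed %d: %.4g ha at %g m\n",
    "  truth: K %s, pasture C %.3f, pasture SRE %.2f, forest SRE %.2f (%s)\n",
    "  observed SE %.4g Mg ha-1 y-1\n"),
    x$size, x$seed, x$area_ha, x$dem$cell_size, x$truth$k_option,
    x$truth$pasture_c, x$truth$pasture_sre, x$truth$forest_sre,
    x$truth$linkage, x$truth$observed_se))
  invisible(x)
}
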