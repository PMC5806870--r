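#' USLE soil loss
#'
#' Elementwise `A = R * K * LS * C * P` (Mg ha^-1 y^-1) on aligned rasters.
#'
#' @param R,K,LS,C,P aligned `sed_raster`s of the USLE factors.
#' @return a `sed_raster` of annual soil loss.
#' @export
usle <- function(R, K, LS, C, P) {
  stop_if_misaligned(R, K, LS, C, P, what = "USLE factor rasters")
  for (r in list(R, K, LS, C, P))
    if (any(r$values < 0, na.rm = TRUE))
      stop("USLE factors must be >= 0", call. = FALSE)
  sed_raster(R$values * K$values * LS$values * C$values * P$values,
             R$cell_size, R$origin)
}

#' Per-cell parameter rasters for one member's resolved parameters
#'
#' Looks up C, P and sediment retention efficiency per land-use class, and
#' K per soil class for the member's erodibility option.
#'
#' @param soilmap `sed_raster` of soil codes.
#' @param landuse `sed_raster` of land-use codes (see [landuse_codes()]).
#' @param params per-class parameter table from [resolve_member_params()]
#'   or [default_landuse_params()].
#' @param k_option `"min"`, `"mean"` or `"max"`.
#' @return list of `sed_raster`s `K`, `C`, `P`, `E`.
#' @export
build_param_rasters <- function(soilmap, landuse, params,
                                k_option = "mean") {
  stop_if_misaligned(soilmap, landuse)
  lu <- landuse$values
  known <- sort(unique(lu[!is.na(lu)]))
  if (!all(known %in% params$code))
    stop("unknown land-use class code(s): ",
         paste(setdiff(known, params$code), collapse = ", "), call. = FALSE)
  lut_c <- lut_p <- lut_e <- rep(NA_real_, max(params$code))
  lut_c[params$code] <- params$c_factor
  lut_p[params$code] <- params$p_factor
  lut_e[params$code] <- params$sre
  mk <- function(lut) sed_raster(matrix(lut[lu], nrow(lu), ncol(lu)),
                                 landuse$cell_size, landuse$origin)
  list(K = k_raster(soilmap, k_option),
       C = mk(lut_c), P = mk(lut_p), E = mk(lut_e))
}

#' Route eroded sediment downslope with vegetative trapping
#'
#' Each cell's eroded mass (soil loss times cell area) travels its D8
#' flowpath. At every strictly downstream hillslope cell `j` a fraction
#' `E_j` of the arriving mass is deposited (credited to the
#' upstream-retention map at `j`) and `1 - E_j` continues; a cell's own
#' retention never acts on its own erosion. Mass reaching a stream cell or
#' leaving the grid is exported; the export map accumulates mass at the
#' cell where it enters the channel (or exits the grid).
#'
#' @param A `sed_raster` of soil loss (Mg ha^-1 y^-1).
#' @param E `sed_raster` of per-cell sediment retention efficiency
#'   (fractions in \[0, 1\]).
#' @param flow a `flow_field`.
#' @return list of class `sediment_outputs`: `soil_loss` (the input A),
#'   `mean_soil_loss` (Mg ha^-1 y^-1), `upstream_retention` and
#'   `export_map` (`sed_raster`s, Mg y^-1), `outlet_export`
#'   (Mg ha^-1 y^-1), `retained_total`, `exported_total`, `total_mass`
#'   (Mg y^-1), `area_ha`.
#' @export
route_sediment <- function(A, E, flow) {
  ev <- E$values
  if (any(ev < 0 | ev > 1, na.rm = TRUE))
    stop("retention efficiency outside [0, 1]", call. = FALSE)
  av <- A$values
  if (!identical(dim(av), dim(flow$direction)))
    stop("soil-loss raster and flow field are misaligned", call. = FALSE)
  cell_ha <- A$cell_size^2 / 1e4
  mass <- av * cell_ha                     # Mg / y eroded per cell
  mass[is.na(mass)] <- 0
  streams <- flow$streams
  dn <- flow$downstream
  retention <- matrix(0, nrow(av), ncol(av))
  export_map <- matrix(0, nrow(av), ncol(av))
  outflow <- matrix(0, nrow(av), ncol(av))   # mass leaving each cell downslope

  # flow$order is sorted high to low elevation, i.e. upstream first
  for (i in flow$order) {
    inflow <- outflow[i]
    if (streams[i]) {
      # channel cells are absorbing: arriving mass and own erosion export here
      export_map[i] <- export_map[i] + inflow + mass[i]
      next
    }
    deposited <- ev[i] * inflow            # own E acts on upstream mass only
    retention[i] <- retention[i] + deposited
    passing <- inflow - deposited + mass[i]
    j <- dn[i]
    if (is.na(j)) {
      export_map[i] <- export_map[i] + passing   # leaves the grid here
    } else {
      outflow[j] <- outflow[j] + passing
    }
  }
  valid <- !is.na(av)
  retention[!valid] <- NA; export_map[!valid] <- NA
  area_ha <- sum(valid) * cell_ha
  exported_total <- sum(export_map, na.rm = TRUE)
  retained_total <- sum(retention, na.rm = TRUE)
  structure(list(
    soil_loss = A,
    mean_soil_loss = mean(av[valid]),
    upstream_retention = sed_raster(retention, A$cell_size, A$origin),
    export_map = sed_raster(export_map, A$cell_size, A$origin),
    outlet_export = exported_total / area_ha,
    retained_total = retained_total,
    exported_total = exported_total,
    total_mass = sum(mass[valid]),
    area_ha = area_ha), class = "sediment_outputs")
}

#' @export
print.sediment_outputs <- function(x, ...) {
  cat(sprintf(paste0(
    "<sediment_outputs> %.4g ha\n",
    "  mean soil loss: %.4g Mg ha-1 y-1\n",
    "  outlet export:  %.4g Mg ha-1 y-1 (%.4g Mg y-1)\n",
    "  retained:       %.4g Mg y-1\n"),
    x$area_ha, x$mean_soil_loss, x$outlet_export, x$exported_total,
    x$retained_total))
  invisible(x)
}

#' Run the USLE + routing model for one parameter set
#'
#' @param bundle a watershed bundle (see [make_reference_watershed()]) or a
#'   list with elements `R`, `soilmap`, `landuse`, `ls`, `flow` and
#'   optionally `p` (support-practice raster, default 1).
#' @param params per-class parameter table.
#' @param k_option erodibility option.
#' @param landuse optional replacement land-use raster (scenario runs).
#' @param erode_streams if `FALSE` (default), channel cells do not produce
#'   USLE soil loss: the sheet-and-rill equation applies to hillslopes, and
#'   in-channel erosion is outside the model's scope. Streams still absorb
#'   and export everything that reaches them.
#' @return a `sediment_outputs` list.
#' @export
run_erosion_model <- function(bundle, params, k_option = "mean",
                              landuse = NULL, erode_streams = FALSE) {
  lu <- if (is.null(landuse)) bundle$landuse else landuse
  pr <- build_param_rasters(bundle$soilmap, lu, params, k_option)
  P <- if (is.null(bundle$p)) {
    sed_raster(matrix(1, nrow(lu$values), ncol(lu$values)) +
               0 * lu$values, lu$cell_size, lu$origin)
  } else bundle$p
  A <- usle(bundle$R, pr$K, bundle$ls, pr$C, P)
  if (!erode_streams) A$values[bundle$flow$streams & !is.na(A$values)] <- 0
  route_sediment(A, pr$E, bundle$flow)
}

#' Summarize sediment outputs by steepness range
#'
#' Totals of soil loss and export binned by the slope of the cell where
#' the quantity originates/arrives, and upstream retention binned by the
#' slope of the retaining cell.
#'
#' @param outputs a `sediment_outputs` list.
#' @param slope `sed_raster` of percent slope.
#' @param bin_edges increasing percent-slope bin edges; a final `Inf` is
#'   appended if absent.
#' @return data.frame with `lo`, `hi`, `soil_loss_mg` (Mg y^-1 mass),
#'   `retention_mg`, `export_mg`.
#' @export
summarize_by_slope <- function(outputs, slope,
                               bin_edges = c(0, 5, 10, 15, 20, 25, 30, 35,
                                             40, 45, 50, 60)) {
  if (any(diff(bin_edges) <= 0)) stop("unsorted bin edges", call. = FALSE)
  if (is.finite(bin_edges[length(bin_edges)])) bin_edges <- c(bin_edges, Inf)
  sv <- slope$values
  if (!identical(dim(sv), dim(outputs$soil_loss$values)))
    stop("slope grid misaligned with outputs", call. = FALSE)
  cell_ha <- outputs$soil_loss$cell_size^2 / 1e4
  loss_mass <- outputs$soil_loss$values * cell_ha
  idx <- findInterval(sv, bin_edges)
  bin_sum <- function(m) {
    v <- tapply(as.vector(m), as.vector(idx), sum, na.rm = TRUE)
    out <- rep(0, length(bin_edges) - 1)
    out[as.integer(names(v))] <- v
    out
  }
  data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
             soil_loss_mg = bin_sum(loss_mass),
             retention_mg = bin_sum(outputs$upstream_retention$values),
             export_mg = bin_sum(outputs$export_map$values))
}
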