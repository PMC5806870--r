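# Land-use class coding shared by all modules. Integer raster codes:
#  1 pasture, 2 forest, 3 eucalyptus, 4 road, 5 water, 6 microdam,
#  7 growing_forest.

#' Land-use class codes
#'
#' Named integer vector mapping land-use class names to the raster codes
#' used by the package.
#' @export
landuse_codes <- function() {
  c(pasture = 1L, forest = 2L, eucalyptus = 3L, road = 4L,
    water = 5L, microdam = 6L, growing_forest = 7L)
}

#' Soil-erodibility table
#'
#' Minimum, mean and maximum USLE K factor (Mg h ha MJ^-1 mm^-1 ha^-1) for
#' the five soil classes of the study region, as measured locally. Soil
#' raster codes are 1..5 in row order.
#'
#' @return data.frame with columns `code`, `soil`, `min`, `mean`, `max`.
#' @export
erodibility_table <- function() {
  data.frame(
    code = 1:5,
    soil = c("Red-Yellow Ultisol", "Ochrept", "Inceptisol",
             "Udorthent", "Fluvent"),
    min  = c(0.0139, 0.0093, 0.0105, 0.0137, 0.0080),
    mean = c(0.0252, 0.0245, 0.0225, 0.0233, 0.0236),
    max  = c(0.0386, 0.0398, 0.0380, 0.0326, 0.0377))
}

#' Calibration ranges of the cover-management (C) factor
#'
#' Literature minima and maxima for the three calibratable land uses.
#'
#' @return data.frame with columns `class`, `min`, `max`.
#' @export
c_factor_ranges <- function() {
  data.frame(class = c("pasture", "forest", "eucalyptus"),
             min = c(0.05, 0.02, 0.12),
             max = c(0.22, 0.09, 0.30))
}

#' Default per-land-use USLE and retention parameters
#'
#' Fixed (non-calibrated) parameter conventions: roads C = 1, water and
#' micro-dams C = 0; micro-dams trap everything (SRE = 1); bare/roads/water
#' have no retention. The support-practice factor P is 1 everywhere (no
#' support practices are modelled; configurable). Calibratable entries
#' (pasture, forest, eucalyptus, growing forest) are filled in by
#' [resolve_member_params()].
#'
#' @return data.frame with columns `class`, `code`, `c_factor`, `p_factor`,
#'   `sre`.
#' @export
default_landuse_params <- function() {
  codes <- landuse_codes()
  data.frame(
    class = names(codes),
    code = unname(codes),
    c_factor = c(0.20, 0.082, 0.141, 1, 0, 0, 0.141),
    p_factor = 1,
    sre = c(0.05, 0.65, 0.35, 0, 0, 1, 0.35))
}

#' Resolve the full parameter table for one calibration member
#'
#' Applies the C-linkage (forest and eucalyptus C follow pasture C, see
#' [linked_c()]), the growing-forest C rule (mean of pasture and forest C),
#' the eucalyptus SRE rule (mean of forest and pasture SRE), and the
#' growing-forest SRE rule (same mean convention).
#'
#' @param pasture_c pasture C factor.
#' @param pasture_sre pasture sediment retention efficiency, fraction.
#' @param forest_sre forest sediment retention efficiency (0.45 or 0.65).
#' @param linkage `"increasing"` or `"decreasing"` C linkage.
#' @param ranges C ranges, see [c_factor_ranges()].
#' @return parameter data.frame as in [default_landuse_params()].
#' @export
resolve_member_params <- function(pasture_c, pasture_sre, forest_sre,
                                  linkage = "increasing",
                                  ranges = c_factor_ranges()) {
  lc <- linked_c(pasture_c, linkage, ranges)
  p <- default_landuse_params()
  p$c_factor[p$class == "pasture"] <- pasture_c
  p$c_factor[p$class == "forest"] <- lc$forest_c
  p$c_factor[p$class == "eucalyptus"] <- lc$eucalyptus_c
  p$c_factor[p$class == "growing_forest"] <- mean(c(pasture_c, lc$forest_c))
  p$sre[p$class == "pasture"] <- pasture_sre
  p$sre[p$class == "forest"] <- forest_sre
  p$sre[p$class == "eucalyptus"] <- eucalyptus_sre(pasture_sre, forest_sre)
  p$sre[p$class == "growing_forest"] <- mean(c(pasture_sre, forest_sre))
  p
}

#' Build a K-factor raster from a soil map
#'
#' @param soilmap `sed_raster` of soil codes (1..5, see
#'   [erodibility_table()]).
#' @param k_option `"min"`, `"mean"` or `"max"` erodibility option.
#' @param table erodibility table.
#' @return `sed_raster` of K.
#' @export
k_raster <- function(soilmap, k_option = c("mean", "min", "max"),
                     table = erodibility_table()) {
  k_option <- match.arg(k_option)
  codes <- soilmap$values
  known <- sort(unique(codes[!is.na(codes)]))
  if (!all(known %in% table$code))
    stop("unknown soil class code(s): ",
         paste(setdiff(known, table$code), collapse = ", "), call. = FALSE)
  lut <- rep(NA_real_, max(table$code))
  lut[table$code] <- table[[k_option]]
  k <- matrix(lut[codes], nrow(codes), ncol(codes))
  sed_raster(k, soilmap$cell_size, soilmap$origin)
}
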