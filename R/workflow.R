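#' Validate a pipeline run configuration
#'
#' A run configuration is a plain named list (serializable as JSON):
#' either `seed` (+ optional `size`) for a synthetic bundle or `dem_path`,
#' `soil_path`, `landuse_path` for ESRI ASCII inputs; plus optional
#' `observed_se`, `tol`, `threshold`, `targets` (forest-% list per
#' strategy), `strategies`, `slope_bins`, `out_dir`.
#'
#' @param config named list.
#' @return the config with defaults filled in; errors on invalid input.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed) && is.null(config$dem_path))
    stop("config needs either `seed` (synthetic) or `dem_path`", call. = FALSE)
  defaults <- list(size = "mini", tol = 0.10,
                   strategies = c("riparian", "steepest", "two_way"),
                   targets = c(10, 25), slope_bins = c(0, 15, 30, 45, 60),
                   out_dir = NULL, noise_sd = 0.2)
  config <- utils::modifyList(defaults, config)
  if (!all(config$strategies %in% c("riparian", "steepest", "two_way")))
    stop("unknown strategy in config", call. = FALSE)
  if (any(diff(config$targets) <= 0))
    stop("targets must be increasing", call. = FALSE)
  config
}

#' Run the full analysis pipeline
#'
#' Terrain, erosivity and observed-export stages (from a synthetic bundle
#' or rasters), ensemble calibration on the current land use, gradual
#' scenario series for each requested strategy, and the strategy
#' comparison. When `out_dir` is set, writes scenario curves and the
#' comparison as CSV, the summary as JSON, and key maps as ESRI ASCII
#' grids; partial outputs are removed if a stage fails.
#'
#' @param config list, see [validate_config()].
#' @return list with `bundle`, `observed_se`, `ensemble`, `scenarios`,
#'   `comparison`, `by_slope`, `summary`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    on_fail <- function() unlink(out_dir, recursive = TRUE)
  } else on_fail <- function() NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      on_fail()
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  bundle <- stage("inputs", {
    if (!is.null(config$seed)) {
      make_reference_watershed(config$seed, config$size,
                               noise_sd = config$noise_sd)
    } else {
      dem <- read_ascii_grid(config$dem_path)
      filled <- fill_depressions(dem)
      flow <- d8_flow(filled, threshold = config$threshold %||% 2000)
      slope <- slope_percent(filled)
      b <- list(dem = dem, dem_filled = filled, flow = flow, slope = slope,
                ls = ls_factor(flow, slope),
                dist = distance_to_stream(flow),
                soilmap = read_ascii_grid(config$soil_path),
                landuse = read_ascii_grid(config$landuse_path))
      if (!is.null(config$gauges_path)) {
        g <- utils::read.csv(config$gauges_path)
        g$date <- as.Date(g$date)
        b$gauges <- g
        b$R <- erosivity_from_gauges(g, filled, config$start, config$end)
      }
      structure(b, class = "watershed_bundle")
    }
  })

  observed_se <- stage("gauging", {
    if (!is.null(config$observed_se)) config$observed_se
    else if (!is.null(bundle$outlet_series)) {
      s <- bundle$outlet_series
      sediment_export_observed(
        data.frame(timestamp = s$timestamp, discharge = s$discharge,
                   turbidity = s$turbidity),
        area_ha = raster_area_ha(bundle$dem))$mean_se
    } else stop("no observed export available", call. = FALSE)
  })

  ensemble <- stage("calibration",
                    run_ensemble(bundle, observed_se, tol = config$tol))
  calibrated <- ensemble$results[ensemble$results$status == "calibrated", ]

  base <- stage("scenarios", anthropized(bundle$landuse))
  series <- stage("scenarios", {
    out <- lapply(config$strategies, function(st)
      scenario_series(st, base, bundle$dist, bundle$slope, config$targets))
    names(out) <- config$strategies
    out
  })
  all_scen <- c(list(base), unlist(series, recursive = FALSE))

  comparison <- stage("comparison",
                      compare_strategies(bundle, all_scen, calibrated))

  by_slope <- stage("summaries", {
    m <- calibrated[1, ]
    params <- resolve_member_params(m$pasture_c, m$pasture_sre,
                                    m$forest_sre, m$linkage)
    out <- run_erosion_model(bundle, params, m$k_option)
    summarize_by_slope(out, bundle$slope, config$slope_bins)
  })

  summary <- list(
    seed = config$seed, size = config$size, observed_se = observed_se,
    calibration = ensemble$summary,
    reductions = comparison[, c("scenario", "strategy", "forest_pct",
                                "soil_loss_red_pct", "se_red_pct")])

  if (!is.null(out_dir)) stage("write", {
    utils::write.csv(ensemble$results,
                     file.path(out_dir, "calibration.csv"), row.names = FALSE)
    utils::write.csv(comparison,
                     file.path(out_dir, "strategy_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(by_slope, file.path(out_dir, "by_slope.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_ascii_grid(bundle$slope, file.path(out_dir, "slope_percent.asc"))
    write_ascii_grid(bundle$ls, file.path(out_dir, "ls_factor.asc"))
  })

  list(bundle = bundle, observed_se = observed_se, ensemble = ensemble,
       scenarios = all_scen, comparison = comparison, by_slope = by_slope,
       summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pick one scenario per strategy at (nearly) equal forest area
#'
#' @param comparison a [compare_strategies()] table.
#' @param target forest fraction (percent) to match.
#' @return rows of `comparison`, one per strategy, whose forest fraction is
#'   nearest the target (ties go to the smaller fraction).
#' @export
equal_area_pick <- function(comparison, target) {
  if (nrow(comparison) == 0) stop("empty comparison table", call. = FALSE)
  strategies <- setdiff(unique(comparison$strategy), "anthropized")
  rows <- lapply(strategies, function(st) {
    sub <- comparison[comparison$strategy == st, , drop = FALSE]
    d <- abs(sub$forest_pct - target)
    if (min(d) > max(diff(range(comparison$forest_pct)), 1))
      stop("target outside scenario curves", call. = FALSE)
    sub[order(d, sub$forest_pct), ][1, ]
  })
  do.call(rbind, rows)
}
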