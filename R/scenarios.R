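# classes that restoration may convert to forest; roads, water and
# micro-dams are never converted
convertible_codes <- function() {
  codes <- landuse_codes()
  unname(codes[c("pasture", "eucalyptus", "growing_forest")])
}

forest_code <- function() unname(landuse_codes()["forest"])

#' Forest fraction of a land-use map
#'
#' Fraction (in percent) of non-nodata cells under forest or growing
#' forest.
#' @param landuse `sed_raster` of land-use codes.
#' @export
forest_fraction <- function(landuse) {
  codes <- landuse_codes()
  lu <- landuse$values
  100 * sum(lu %in% codes[c("forest", "growing_forest")]) / sum(!is.na(lu))
}

new_scenario <- function(name, strategy, landuse, parameter = NULL) {
  structure(list(name = name, strategy = strategy, landuse = landuse,
                 parameter = parameter,
                 forest_fraction = forest_fraction(landuse)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (%s): %.1f%% forest\n",
              x$name, x$strategy, x$forest_fraction))
  invisible(x)
}

#' Anthropized (no-conservation) counterfactual
#'
#' Converts forest, growing forest, and micro-dam cells to pasture; roads,
#' water and eucalyptus are unchanged. This is the baseline from which the
#' gradual restoration series start.
#'
#' @param landuse `sed_raster` of land-use codes.
#' @return a `scenario`.
#' @export
anthropized <- function(landuse) {
  codes <- landuse_codes()
  lu <- landuse$values
  lu[lu %in% codes[c("forest", "growing_forest", "microdam")]] <-
    codes[["pasture"]]
  new_scenario("anthropized", "anthropized",
               sed_raster(lu, landuse$cell_size, landuse$origin))
}

#' Riparian restoration scenario
#'
#' Converts convertible cells (pasture, eucalyptus, growing forest) within
#' `width` metres of the stream network (Euclidean cell-centre distance,
#' per side) to forest. Channel cells themselves (distance 0) are banks'
#' neighbours, not banks, and are left unchanged.
#'
#' @param base a `scenario` (typically [anthropized()]).
#' @param dist `sed_raster` of distance to the nearest stream cell (m).
#' @param width buffer width (m), >= 0.
#' @return a `scenario`.
#' @export
riparian_scenario <- function(base, dist, width) {
  if (width < 0) stop("width must be >= 0", call. = FALSE)
  lu <- base$landuse$values
  conv <- lu %in% convertible_codes() & !is.na(dist$values) &
    dist$values > 0 & dist$values <= width
  lu[conv] <- forest_code()
  new_scenario(sprintf("riparian_%gm", width), "riparian",
               sed_raster(lu, base$landuse$cell_size, base$landuse$origin),
               parameter = c(width = width))
}

#' Steepest-slopes restoration scenario
#'
#' Converts convertible cells with slope strictly above `threshold`
#' (percent) to forest.
#'
#' @param base a `scenario`.
#' @param slope `sed_raster` of percent slope.
#' @param threshold percent-slope threshold, >= 0.
#' @return a `scenario`.
#' @export
steepest_scenario <- function(base, slope, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  lu <- base$landuse$values
  conv <- lu %in% convertible_codes() & !is.na(slope$values) &
          slope$values > threshold
  lu[conv] <- forest_code()
  new_scenario(sprintf("steepest_%g%%", threshold), "steepest",
               sed_raster(lu, base$landuse$cell_size, base$landuse$origin),
               parameter = c(threshold = threshold))
}

#' Two-way (riparian + steepest) restoration scenario
#'
#' Union of the riparian and steepest conversion sets at the given
#' parameters.
#'
#' @param base a `scenario`.
#' @param dist distance-to-stream raster.
#' @param slope percent-slope raster.
#' @param width riparian width (m).
#' @param threshold slope threshold (%).
#' @return a `scenario`.
#' @export
two_way_scenario <- function(base, dist, slope, width, threshold) {
  s1 <- riparian_scenario(base, dist, width)
  lu <- s1$landuse$values
  conv <- lu %in% convertible_codes() & !is.na(slope$values) &
          slope$values > threshold
  lu[conv] <- forest_code()
  new_scenario(sprintf("two_way_%gm_%g%%", width, threshold), "two_way",
               sed_raster(lu, base$landuse$cell_size, base$landuse$origin),
               parameter = c(width = width, threshold = threshold))
}

# forest fraction that the riparian mechanism alone reaches at `width`
riparian_fraction <- function(base, dist, width)
  forest_fraction(riparian_scenario(base, dist, width)$landuse)
steepest_fraction <- function(base, slope, threshold)
  forest_fraction(steepest_scenario(base, slope, threshold)$landuse)

# riparian width converting about k convertible cells: the fraction-width
# relation is a step function over the discrete distance values, so pick
# the step whose cell count is nearest k (ties inflate whole rings at once)
width_for_count <- function(base, dist, k) {
  d <- dist$values[base$landuse$values %in% convertible_codes()]
  d <- sort(d[d > 0])
  if (k < 1) return(0)
  u <- unique(d)
  cnt <- cumsum(as.numeric(table(factor(d, levels = u))))
  u[which.min(abs(cnt - k))]
}

# slope threshold converting >= k convertible cells: just below the k-th
# largest slope among convertible cells
threshold_for_count <- function(base, slope, k) {
  s <- sort(slope$values[base$landuse$values %in% convertible_codes()],
            decreasing = TRUE)
  if (k < 1) max(s) + 1 else s[min(k, length(s))] - 1e-9
}

#' Build a gradual scenario series hitting target forest fractions
#'
#' For each target forest fraction the strategy parameter (riparian width,
#' slope threshold, or the two-way pair) is found by bisection so that the
#' realized fraction is within `tol_pct` of the target. For the two-way
#' strategy, the pair is chosen so that each mechanism alone would convert
#' (as nearly as possible) the same new-forest area.
#'
#' @param strategy `"riparian"`, `"steepest"` or `"two_way"`.
#' @param base base `scenario` (typically [anthropized()]).
#' @param dist distance-to-stream raster.
#' @param slope percent-slope raster.
#' @param targets increasing forest-fraction targets (percent).
#' @param tol_pct acceptable absolute deviation from the target (percent
#'   points).
#' @return list of `scenario`s (base prepended for target 0).
#' @export
scenario_series <- function(strategy = c("riparian", "steepest", "two_way"),
                            base, dist, slope, targets, tol_pct = 0.5) {
  strategy <- match.arg(strategy)
  if (is.unsorted(targets, strictly = TRUE))
    stop("targets must be increasing", call. = FALSE)
  base_frac <- base$forest_fraction
  n <- sum(!is.na(base$landuse$values))
  n_conv <- sum(base$landuse$values %in% convertible_codes())
  max_frac <- base_frac + 100 * n_conv / n
  out <- list()
  for (tg in targets) {
    if (tg <= base_frac + tol_pct) { out <- c(out, list(base)); next }
    if (tg > max_frac + tol_pct)
      stop(sprintf("target %.1f%% unreachable for %s (max %.1f%%)",
                   tg, strategy, max_frac), call. = FALSE)
    k <- round((tg - base_frac) / 100 * n)   # convertible cells needed
    sc <- switch(strategy,
      riparian = riparian_scenario(base, dist, width_for_count(base, dist, k)),
      steepest = steepest_scenario(base, slope,
                                   threshold_for_count(base, slope, k)),
      two_way = {
        # find the equal per-mechanism count a whose union converts k cells
        # (the union is monotone in a; integer bisection)
        union_sc <- function(a)
          two_way_scenario(base, dist, slope,
                           width_for_count(base, dist, a),
                           threshold_for_count(base, slope, a))
        lo <- 1L; hi <- n_conv
        while (hi - lo > 1L) {
          mid <- (lo + hi) %/% 2L
          f <- forest_fraction(union_sc(mid)$landuse)
          if (f < tg) lo <- mid else hi <- mid
        }
        cand <- list(union_sc(lo), union_sc(hi))
        dev <- vapply(cand, function(s) abs(s$forest_fraction - tg),
                      numeric(1))
        cand[[which.min(dev)]]
      })
    if (abs(sc$forest_fraction - tg) > tol_pct)
      warning(sprintf("%s: realized %.2f%% vs target %.2f%%", strategy,
                      sc$forest_fraction, tg), call. = FALSE)
    out <- c(out, list(sc))
  }
  out
}

#' Run scenarios across the calibrated ensemble and compare strategies
#'
#' Runs the erosion model for every scenario under every calibrated
#' ensemble member and reports, per scenario, the ensemble mean and range
#' of mean soil loss and outlet sediment export, plus percent reductions
#' relative to the baseline scenario (`100 * (1 - value / baseline)`,
#' member-wise before averaging).
#'
#' @param bundle watershed bundle.
#' @param scenarios list of `scenario`s; the first is the baseline.
#' @param calibrated data.frame of calibrated members (rows of
#'   `run_ensemble()$results` with status `"calibrated"`).
#' @return data.frame with one row per scenario x summary: columns
#'   `scenario`, `strategy`, `forest_pct`, `soil_loss_mean/min/max`,
#'   `se_mean/min/max`, `soil_loss_red_pct`, `se_red_pct`.
#' @export
compare_strategies <- function(bundle, scenarios, calibrated) {
  if (nrow(calibrated) == 0) stop("no calibrated members", call. = FALSE)
  runs <- lapply(scenarios, function(sc) {
    per_member <- lapply(seq_len(nrow(calibrated)), function(i) {
      m <- calibrated[i, ]
      params <- resolve_member_params(m$pasture_c, m$pasture_sre,
                                      m$forest_sre, m$linkage)
      out <- run_erosion_model(bundle, params, m$k_option,
                               landuse = sc$landuse)
      c(soil_loss = out$mean_soil_loss, se = out$outlet_export)
    })
    do.call(rbind, per_member)
  })
  base <- runs[[1]]
  if (any(base[, "se"] <= 0)) stop("baseline export is zero", call. = FALSE)
  rows <- lapply(seq_along(scenarios), function(k) {
    r <- runs[[k]]
    red <- 100 * (1 - r / base)
    data.frame(
      scenario = scenarios[[k]]$name, strategy = scenarios[[k]]$strategy,
      forest_pct = scenarios[[k]]$forest_fraction,
      soil_loss_mean = mean(r[, "soil_loss"]),
      soil_loss_min = min(r[, "soil_loss"]),
      soil_loss_max = max(r[, "soil_loss"]),
      se_mean = mean(r[, "se"]), se_min = min(r[, "se"]),
      se_max = max(r[, "se"]),
      soil_loss_red_pct = mean(red[, "soil_loss"]),
      se_red_pct = mean(red[, "se"]))
  })
  do.call(rbind, rows)
}
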