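#' Rating curve constructor
#'
#' A piecewise curve on discharge: ordered segments over half-open domains
#' `[lo, hi)` partitioning `[0, Inf)`, each either a power law `a * Q^b` or
#' linear `a * Q + c`. Evaluated output is clamped at 0.
#'
#' @param segments data.frame with columns `lo`, `hi`, `form` ("power" or
#'   "linear"), `a`, `b` (exponent for power, intercept for linear).
#' @return object of class `rating_curve`.
#' @export
rating_curve <- function(segments) {
  stopifnot(all(c("lo", "hi", "form", "a", "b") %in% names(segments)))
  segments <- segments[order(segments$lo), , drop = FALSE]
  if (segments$lo[1] != 0 || !is.infinite(segments$hi[nrow(segments)]) ||
      (nrow(segments) > 1 &&
       any(segments$hi[-nrow(segments)] != segments$lo[-1])))
    stop("segment domains must partition [0, Inf)", call. = FALSE)
  if (!all(is.finite(segments$a)) || !all(is.finite(segments$b)))
    stop("non-finite coefficients", call. = FALSE)
  structure(list(segments = segments), class = "rating_curve")
}

#' @export
print.rating_curve <- function(x, ...) {
  cat("<rating_curve>\n")
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    f <- if (s$form == "power") sprintf("%.4g * Q^%.4g", s$a, s$b)
         else sprintf("%.4g * Q + %.4g", s$a, s$b)
    cat(sprintf("  [%g, %g): %s\n", s$lo, s$hi, f))
  }
  invisible(x)
}

#' Default turbidity-discharge rating curve
#'
#' The packaged three-segment curve for the study outlet: power laws below
#' 0.23 and between 0.23 and 0.95 m3/s, linear above 0.95 m3/s.
#'
#' @return a `rating_curve` mapping discharge (m3/s) to turbidity (NTU).
#' @export
default_turbidity_curve <- function() {
  rating_curve(data.frame(
    lo = c(0, 0.23, 0.95), hi = c(0.23, 0.95, Inf),
    form = c("power", "power", "linear"),
    a = c(94.58, 308.92, 560.42),
    b = c(1.14, 1.90, -252.3)))
}

#' Evaluate a turbidity rating curve
#'
#' @param q discharge (m3/s), >= 0.
#' @param curve a `rating_curve`; defaults to the packaged curve.
#' @return turbidity (NTU), clamped at 0.
#' @export
turbidity_from_discharge <- function(q, curve = default_turbidity_curve()) {
  if (any(q < 0, na.rm = TRUE)) stop("discharge must be >= 0", call. = FALSE)
  seg <- curve$segments
  out <- rep(NA_real_, length(q))
  for (i in seq_len(nrow(seg))) {
    sel <- q >= seg$lo[i] & q < seg$hi[i]
    out[sel] <- if (seg$form[i] == "power") seg$a[i] * q[sel]^seg$b[i]
                else seg$a[i] * q[sel] + seg$b[i]
  }
  pmax(out, 0)
}

#' Suspended-sediment concentration from turbidity
#'
#' Linear turbidity-to-concentration transfer `SS = 1.114 * TU + 1.4731`
#' (mg/L from NTU), from a regional optical calibration.
#'
#' @param tu turbidity (NTU), >= 0.
#' @return suspended-sediment concentration (mg/L).
#' @export
suspended_sediment <- function(tu) {
  if (any(tu < 0, na.rm = TRUE)) stop("turbidity must be >= 0", call. = FALSE)
  1.114 * tu + 1.4731
}

#' Fit a stage-discharge rating curve
#'
#' Single-segment power law `Q = a * (h - h0)^b` fitted by least squares on
#' the log scale, with the datum offset `h0` profiled out by 1-D
#' optimization.
#'
#' @param pairs data.frame with columns `stage` (m) and `discharge` (m3/s).
#' @return list with `a`, `b`, `h0` and `predict(stage)` closure (clamped
#'   at 0 for stage <= h0).
#' @export
fit_stage_discharge <- function(pairs) {
  if (nrow(pairs) < 4) stop("need at least 4 stage-discharge pairs", call. = FALSE)
  if (anyDuplicated(pairs$stage)) stop("stages must be distinct", call. = FALSE)
  o <- order(pairs$stage)
  if (any(diff(pairs$discharge[o]) <= 0)) {
    bad <- which(diff(pairs$discharge[o]) <= 0)
    stop("non-monotone stage-discharge pairs at sorted positions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  h <- pairs$stage; q <- pairs$discharge
  sse <- function(h0) {
    fit <- stats::lm(log(q) ~ log(h - h0))
    sum(stats::resid(fit)^2)
  }
  upper <- min(h) - 1e-6 * max(diff(range(h)), 1e-6)
  opt <- stats::optimize(sse, lower = min(h) - diff(range(h)) * 3, upper = upper)
  h0 <- opt$minimum
  fit <- stats::lm(log(q) ~ log(h - h0))
  a <- exp(stats::coef(fit)[[1]]); b <- stats::coef(fit)[[2]]
  list(a = a, b = b, h0 = h0,
       predict = function(stage) ifelse(stage > h0, a * (stage - h0)^b, 0))
}

#' Fit a piecewise turbidity-discharge rating curve
#'
#' Splits the pairs at the given discharge breakpoints; fits each segment by
#' least squares on the log scale (power form) except the last, which is
#' fitted linearly. With zero breakpoints a single linear segment is fitted.
#'
#' @param pairs data.frame with columns `discharge` and `turbidity`.
#' @param breakpoints increasing discharge values splitting the domain.
#' @return a `rating_curve`.
#' @export
fit_turbidity_curve <- function(pairs, breakpoints = numeric()) {
  edges <- c(0, sort(breakpoints), Inf)
  n_seg <- length(edges) - 1
  seg <- data.frame(lo = edges[-length(edges)], hi = edges[-1],
                    form = c(rep("power", n_seg - 1), "linear"),
                    a = NA_real_, b = NA_real_)
  for (i in seq_len(n_seg)) {
    sel <- pairs$discharge >= seg$lo[i] & pairs$discharge < seg$hi[i]
    if (sum(sel) < 2)
      stop(sprintf("segment [%g, %g) has fewer than 2 pairs",
                   seg$lo[i], seg$hi[i]), call. = FALSE)
    q <- pairs$discharge[sel]; tu <- pairs$turbidity[sel]
    if (seg$form[i] == "power") {
      fit <- stats::lm(log(tu) ~ log(q))
      seg$a[i] <- exp(stats::coef(fit)[[1]]); seg$b[i] <- stats::coef(fit)[[2]]
    } else {
      fit <- stats::lm(tu ~ q)
      seg$a[i] <- stats::coef(fit)[[2]]; seg$b[i] <- stats::coef(fit)[[1]]
    }
  }
  rating_curve(seg)
}

#' Observed sediment export from a gauge series
#'
#' Converts each record's discharge and suspended-sediment concentration to
#' an instantaneous areal sediment flux `31.536 * Q * SS / DA`
#' (Mg ha^-1 y^-1; the constant converts m3/s * mg/L = g/s to Mg/y), then
#' averages over each hydrological year (Oct-Sep) and over the period.
#'
#' @param series data.frame with columns `timestamp` (POSIXct or Date),
#'   `discharge` (m3/s) and either `ss` (mg/L) or `turbidity` (NTU; then
#'   `ss` is derived via [suspended_sediment()]).
#' @param area_ha drainage area DA (ha), > 0.
#' @return list with `annual` (data.frame `year`, `se`), `mean_se`
#'   (Mg ha^-1 y^-1), `area_ha`.
#' @export
sediment_export_observed <- function(series, area_ha) {
  if (area_ha <= 0) stop("drainage area must be > 0", call. = FALSE)
  if (is.null(series$ss)) {
    if (is.null(series$turbidity))
      stop("series needs `ss` or `turbidity`", call. = FALSE)
    series$ss <- suspended_sediment(series$turbidity)
  }
  if (is.unsorted(as.numeric(series$timestamp), strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  se_inst <- 31.536 * series$discharge * series$ss / area_ha
  t <- as.POSIXlt(series$timestamp)
  hydro_year <- t$year + 1900 + as.integer(t$mon >= 9)  # Oct starts next HY
  annual <- stats::aggregate(se_inst, by = list(year = hydro_year), FUN = mean)
  names(annual)[2] <- "se"
  empty <- !is.finite(annual$se)
  if (any(empty)) {
    warning(sum(empty), " empty hydrological year(s) skipped", call. = FALSE)
    annual <- annual[!empty, , drop = FALSE]
  }
  list(annual = annual, mean_se = mean(annual$se), area_ha = area_ha)
}

#' Percentage frequency distribution of a series variable
#'
#' @param x numeric vector.
#' @param bins either a single bin count or a vector of increasing bin
#'   edges spanning the data.
#' @return data.frame with columns `lo`, `hi`, `percent` summing to 100.
#' @export
frequency_distribution <- function(x, bins = 10) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty series", call. = FALSE)
  if (length(bins) == 1) {
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
  } else edges <- bins
  if (any(diff(edges) <= 0)) stop("zero-width or unsorted bin", call. = FALSE)
  if (any(x < edges[1] | x > edges[length(edges)]))
    stop("values outside bin range", call. = FALSE)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  data.frame(lo = edges[-length(edges)], hi = edges[-1],
             percent = 100 * counts / length(x))
}
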