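#' Buffer trapping efficiency from per-pixel retention
#'
#' A homogeneous vegetation buffer of width `l` at pixel size `r` spans
#' `n = l/r` pixels, each trapping a fraction `sre` of the sediment passing
#' through it. Assuming no soil loss inside the buffer, the whole-buffer
#' trapping efficiency is `Te = 1 - (1 - sre)^(l/r)`.
#'
#' @param sre per-pixel sediment retention efficiency, fraction in \[0, 1\].
#' @param width buffer width l (m), >= 0.
#' @param pixel pixel size r (m), > 0.
#' @return trapping efficiency, fraction in \[0, 1\].
#' @export
trapping_from_sre <- function(sre, width, pixel) {
  if (any(pixel <= 0)) stop("pixel size must be > 0", call. = FALSE)
  if (any(sre < 0 | sre > 1)) stop("sre must be in [0, 1]", call. = FALSE)
  if (any(width < 0)) stop("width must be >= 0", call. = FALSE)
  # -expm1(n * log1p(-sre)) = 1 - (1 - sre)^n, accurate near both ends
  -expm1(width / pixel * log1p(-sre))
}

#' Per-pixel retention from buffer trapping efficiency
#'
#' Exact algebraic inverse of [trapping_from_sre()]:
#' `sre = 1 - (1 - Te)^(r/l)`.
#'
#' @param te whole-buffer trapping efficiency, fraction in \[0, 1).
#' @param width buffer width l (m), > 0.
#' @param pixel pixel size r (m), > 0.
#' @return per-pixel sediment retention efficiency.
#' @export
sre_from_trapping <- function(te, width, pixel) {
  if (any(pixel <= 0)) stop("pixel size must be > 0", call. = FALSE)
  if (any(width <= 0)) stop("width must be > 0", call. = FALSE)
  if (any(te < 0 | te >= 1))
    stop("te must be in [0, 1); te = 1 has no finite-width inverse",
         call. = FALSE)
  -expm1(pixel / width * log1p(-te))
}

#' Fit a per-pixel SRE band to literature width-trapping points
#'
#' Given literature points (buffer width, observed trapping efficiency) and
#' candidate per-pixel SRE values, selects the pair of candidates whose
#' trapping curves jointly minimize the total squared deviation from the
#' points while their envelope brackets at least `coverage` of them.
#'
#' @param points data.frame with columns `width` (m) and `te` (fraction).
#' @param pixel pixel size r (m).
#' @param candidates numeric vector of candidate SRE values.
#' @param coverage minimum fraction of points the band must bracket.
#' @return list with `sre_lo`, `sre_hi`, `coverage` (fraction bracketed),
#'   `sse` (summed squared deviation of the two curves).
#' @export
fit_sre_band <- function(points, pixel = 5,
                         candidates = seq(0.05, 0.95, by = 0.05),
                         coverage = 0.8) {
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  candidates <- sort(unique(candidates))
  pred <- sapply(candidates, function(s)
    trapping_from_sre(s, points$width, pixel))
  pred <- matrix(pred, nrow = nrow(points))
  combos <- expand.grid(lo = seq_along(candidates), hi = seq_along(candidates))
  combos <- combos[combos$lo <= combos$hi, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    lo <- combos$lo[i]; hi <- combos$hi[i]
    cov <- mean(points$te >= pred[, lo] - 1e-12 &
                points$te <= pred[, hi] + 1e-12)
    sse <- sum((points$te - pred[, lo])^2) + sum((points$te - pred[, hi])^2)
    cand <- list(sre_lo = candidates[lo], sre_hi = candidates[hi],
                 coverage = cov, sse = sse)
    ok <- cov >= coverage
    if (ok && (is.null(best) || !best$ok || sse < best$sse))
      best <- c(cand, ok = TRUE)
    if (is.null(best)) best <- c(cand, ok = FALSE)
  }
  if (!best$ok) {
    warning("no candidate pair brackets ", coverage * 100,
            "% of points; returning the widest pair", call. = FALSE)
    best <- list(sre_lo = min(candidates), sre_hi = max(candidates),
                 coverage = mean(points$te >= pred[, 1] - 1e-12 &
                                 points$te <= pred[, ncol(pred)] + 1e-12),
                 sse = sum((points$te - pred[, 1])^2) +
                       sum((points$te - pred[, ncol(pred)])^2),
                 ok = FALSE)
  }
  best[c("sre_lo", "sre_hi", "coverage", "sse")]
}

#' Literature-style buffer trapping points (synthetic stand-in)
#'
#' Loads the packaged width-trapping table. The shipped values are a
#' synthetic stand-in emulating the spread of published vegetative filter
#' strip experiments (trapping rising steeply over the first ~10-30 m of
#' buffer width); they are not digitized measurements and are never
#' asserted numerically in tests.
#'
#' @return data.frame with columns `width`, `te`, `source`.
#' @export
buffer_literature_points <- function() {
  path <- system.file("extdata", "buffer_trapping_synthetic.csv",
                      package = "sedscape", mustWork = TRUE)
  utils::read.csv(path)
}
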