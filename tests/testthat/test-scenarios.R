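test_that("the anthropized counterfactual strips forest and micro-dams", {
  b <- ref_bundle()
  sc <- anthropized(b$landuse)
  codes <- landuse_codes()
  expect_equal(sc$forest_fraction, 0)
  expect_false(any(sc$landuse$values %in%
                   codes[c("forest", "growing_forest", "microdam")]))
  # roads and eucalyptus persist
  expect_equal(sum(sc$landuse$values == codes["road"]),
               sum(b$landuse$values == codes["road"], na.rm = TRUE))
  expect_equal(sum(sc$landuse$values == codes["eucalyptus"]),
               sum(b$landuse$values == codes["eucalyptus"], na.rm = TRUE))
  # a map with nothing to strip is unchanged
  plain <- sed_raster(matrix(codes[["pasture"]], 8, 8), 5)
  expect_equal(anthropized(plain)$landuse$values, plain$values)
})

test_that("riparian conversion follows cell-centre geometry", {
  codes <- landuse_codes()
  # 11-column pasture grid, stream in the central column, 5 m cells
  lu <- sed_raster(matrix(codes[["pasture"]], 9, 11), 5)
  st <- matrix(FALSE, 9, 11); st[, 6] <- TRUE
  dist <- distance_to_stream(st, cell_size = 5)
  base <- anthropized(lu)
  r0 <- riparian_scenario(base, dist, 0)
  expect_equal(r0$landuse$values, lu$values)
  r5 <- riparian_scenario(base, dist, 5)
  expect_true(all(r5$landuse$values[, c(5, 7)] == codes[["forest"]]))
  expect_true(all(r5$landuse$values[, c(4, 8)] == codes[["pasture"]]))
  # the channel column itself is not planted
  expect_true(all(r5$landuse$values[, 6] == codes[["pasture"]]))
  # fraction is non-decreasing in width
  f <- vapply(c(0, 5, 10, 20, 30), function(w)
    riparian_scenario(base, dist, w)$forest_fraction, numeric(1))
  expect_true(all(diff(f) >= 0))
  expect_error(riparian_scenario(base, dist, -1), ">= 0")
})

test_that("steepest-slope conversion honours the threshold", {
  b <- ref_bundle()
  base <- anthropized(b$landuse)
  above_max <- steepest_scenario(base, b$slope, 1000)
  expect_equal(above_max$landuse$values, base$landuse$values)
  all_in <- steepest_scenario(base, b$slope, 0)
  conv <- base$landuse$values %in% c(1L, 3L, 7L)
  expect_true(all(all_in$landuse$values[conv & b$slope$values > 0] ==
                  landuse_codes()[["forest"]]))
  f <- vapply(c(60, 45, 30, 15, 0), function(th)
    steepest_scenario(base, b$slope, th)$forest_fraction, numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("two-way unions the riparian and steepest conversion sets", {
  b <- ref_bundle()
  base <- anthropized(b$landuse)
  tw <- two_way_scenario(base, b$dist, b$slope, 10, 45)
  rp <- riparian_scenario(base, b$dist, 10)
  st <- steepest_scenario(base, b$slope, 45)
  fcode <- landuse_codes()[["forest"]]
  expect_true(all(tw$landuse$values[rp$landuse$values == fcode] == fcode))
  expect_true(all(tw$landuse$values[st$landuse$values == fcode] == fcode))
  none <- two_way_scenario(base, b$dist, b$slope, 0, 1000)
  expect_equal(none$landuse$values, base$landuse$values)
})

test_that("scenario maps differ from the base only on convertible classes", {
  b <- ref_bundle()
  base <- anthropized(b$landuse)
  for (sc in list(riparian_scenario(base, b$dist, 20),
                  steepest_scenario(base, b$slope, 40),
                  two_way_scenario(base, b$dist, b$slope, 10, 50))) {
    changed <- which(sc$landuse$values != base$landuse$values)
    expect_true(all(base$landuse$values[changed] %in% c(1L, 3L, 7L)))
    expect_true(all(sc$landuse$values[changed] ==
                    landuse_codes()[["forest"]]))
  }
})

test_that("scenario series hit their forest-fraction targets", {
  b <- ref_bundle()
  base <- anthropized(b$landuse)
  for (st in c("riparian", "steepest", "two_way")) {
    sers <- suppressWarnings(
      scenario_series(st, base, b$dist, b$slope, c(25, 40)))
    fr <- vapply(sers, function(s) s$forest_fraction, numeric(1))
    expect_true(all(diff(fr) > 0))
    expect_lt(abs(fr[1] - 25), 3)   # ring granularity on the mini grid
    expect_lt(abs(fr[2] - 40), 3)
  }
  expect_error(scenario_series("steepest", base, b$dist, b$slope, 99),
               "unreachable")
  expect_error(scenario_series("riparian", base, b$dist, b$slope, c(30, 20)),
               "increasing")
})

test_that("strategy comparison reports member-wise reductions", {
  b <- ref_bundle()
  ens <- ref_ensemble()
  cal <- ens$results[ens$results$status == "calibrated", ][1:3, ]
  base <- anthropized(b$landuse)
  rp <- riparian_scenario(base, b$dist, 15)
  cmp <- compare_strategies(b, list(base, rp), cal)
  expect_equal(cmp$soil_loss_red_pct[1], 0)
  expect_equal(cmp$se_red_pct[1], 0)
  # adding forest only reduces both responses
  expect_gt(cmp$se_red_pct[2], 0)
  expect_gt(cmp$soil_loss_red_pct[2], 0)
  expect_lte(cmp$se_red_pct[2], 100)
  expect_equal(cmp$se_min[1] <= cmp$se_mean[1], TRUE)
})
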