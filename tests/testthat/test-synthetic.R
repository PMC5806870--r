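test_that("the DEM generator is deterministic and spans the slope range", {
  a <- make_dem(seed = 11)
  b <- make_dem(seed = 11)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, make_dem(seed = 12)$values))
  # plane limit: no valley, no noise
  plane <- make_dem(32, 32, cell_size = 5, relief = 31, roughness = 0,
                    valley_fraction = 0, seed = 1)
  s <- slope_percent(plane)$values
  expect_equal(s[16, 16], 100 * 31 / (31 * 5), tolerance = 1e-6)
  # default surface covers the steepness bins used in summaries
  sl <- slope_percent(fill_depressions(make_dem(seed = 2)))$values
  expect_gt(max(sl), 60)
  h <- frequency_distribution(as.vector(sl), bins = c(0, 15, 30, 45, 60, 200))
  expect_true(all(h$percent > 0))
})

test_that("soil maps contain the expected classes with packaged erodibility", {
  b <- ref_bundle()
  expect_setequal(unique(as.vector(b$soilmap$values)), 1:5)
  # class patches are contiguous enough to have interior runs
  expect_gt(mean(diff(as.vector(b$soilmap$values)) == 0), 0.8)
  one <- make_soils(sed_raster(matrix(0, 20, 20), 5),
                    table = erodibility_table()[2, ], seed = 1, n_patches = 4)
  expect_equal(unique(as.vector(one$values)), 2)
  expect_equal(k_raster(one, "mean")$values[1, 1], 0.0245)
  expect_equal(k_raster(one, "min")$values[1, 1], 0.0093)
  expect_equal(k_raster(one, "max")$values[1, 1], 0.0398)
  # Fluvent hugs the streams when a mask is given
  st <- b$flow$streams
  expect_true(all(b$soilmap$values[st] == 5L))
})

test_that("land-use fractions land within a percent of their targets", {
  b <- ref_bundle()
  codes <- landuse_codes()
  n <- sum(!is.na(b$landuse$values))
  frac <- function(code) 100 * sum(b$landuse$values == code, na.rm = TRUE) / n
  expect_lt(abs(frac(codes["forest"]) - 25), 1)
  expect_lt(abs(frac(codes["road"]) - 2), 1)
  expect_lt(abs(frac(codes["eucalyptus"]) - 2), 1)
  expect_lt(abs(frac(codes["microdam"]) - 0.1), 1)
  expect_lt(abs(frac(codes["pasture"]) - 70.9), 2)
  # micro-dams sit next to roads
  dams <- which(b$landuse$values == codes[["microdam"]], arr.ind = TRUE)
  roads <- which(b$landuse$values == codes[["road"]], arr.ind = TRUE)
  for (i in seq_len(nrow(dams))) {
    d <- max(abs(sweep(roads, 2, dams[i, ])), 0)
    expect_lte(min(pmax(abs(roads[, 1] - dams[i, 1]),
                        abs(roads[, 2] - dams[i, 2]))), 1)
  }
  # degenerate request: pasture only
  solo <- make_landuse(sed_raster(matrix(0, 20, 20), 5),
                       streams = matrix(FALSE, 20, 20),
                       slope = sed_raster(matrix(10, 20, 20), 5),
                       fractions = c(forest = 0, road = 0, eucalyptus = 0,
                                     microdam = 0),
                       seed = 1, dist = sed_raster(matrix(30, 20, 20), 5))
  expect_true(all(solo$values == landuse_codes()[["pasture"]]))
  expect_error(make_landuse(sed_raster(matrix(0, 20, 20), 5),
                            matrix(FALSE, 20, 20),
                            sed_raster(matrix(10, 20, 20), 5),
                            fractions = c(forest = 90, road = 20)),
               "100")
})

test_that("outlet series are deterministic and closed under the rating math", {
  clean <- make_outlet_series(2.5, 1200, noise_sd = 0, seed = 5)
  again <- make_outlet_series(2.5, 1200, noise_sd = 0, seed = 5)
  expect_identical(clean, again)
  # noise-free: recomputing export from the series returns the target
  # (mean of hydro-year means differs from the flat record mean only
  # through unequal record counts per year)
  obs <- sediment_export_observed(clean, 1200)
  expect_equal(obs$mean_se, attr(clean, "implied_se"), tolerance = 1e-3)
  expect_equal(mean(31.536 * clean$discharge *
                    suspended_sediment(clean$turbidity) / 1200), 2.5,
               tolerance = 1e-8)
  # doubling discharge raises export superlinearly (convex rating curve)
  dbl <- clean; dbl$discharge <- 2 * clean$discharge
  dbl$turbidity <- turbidity_from_discharge(dbl$discharge)
  expect_gt(sediment_export_observed(dbl, 1200)$mean_se, 2 * 2.5)
})

test_that("reference bundles are reproducible and closed under the model", {
  b <- ref_bundle()
  expect_equal(b$area_ha, 10.24)
  # truth closure: rerunning the forward model reproduces the stored export
  params <- resolve_member_params(b$truth$pasture_c, b$truth$pasture_sre,
                                  b$truth$forest_sre, b$truth$linkage)
  rerun <- run_erosion_model(b, params, b$truth$k_option)
  expect_equal(rerun$outlet_export, b$truth$observed_se, tolerance = 1e-9)
  expect_equal(rerun$mean_soil_loss, b$truth$mean_soil_loss, tolerance = 1e-9)
  # gauge series implies the same export up to sampling noise
  expect_equal(b$truth$gauge_implied_se, b$truth$observed_se,
               tolerance = 1e-6)
  # determinism under the seed
  b2 <- make_reference_watershed(1)
  expect_identical(b2$dem$values, b$dem$values)
  expect_identical(b2$landuse$values, b$landuse$values)
  expect_identical(b2$truth, b$truth)
  # the full-scale geometry covers the stated watershed area within 1%
  full_dem <- make_dem(693, 693, cell_size = 5, relief = 300, seed = 1)
  expect_lt(abs(raster_area_ha(full_dem) - 1200) / 1200, 0.01)
})
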