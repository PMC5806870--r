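test_that("USLE is the elementwise factor product", {
  mk <- function(v) sed_raster(matrix(v, 3, 3), 5)
  A <- usle(mk(6873), mk(0.0252), mk(1), mk(0.22), mk(1))
  expect_equal(A$values[1, 1], 6873 * 0.0252 * 0.22, tolerance = 1e-12)
  expect_equal(A$values[2, 2], 38.10, tolerance = 1e-3)
  expect_equal(usle(mk(6873), mk(0.0252), mk(1), mk(0), mk(1))$values,
               matrix(0, 3, 3))
  A2 <- usle(mk(6873), mk(0.0252), mk(2), mk(0.22), mk(1))
  expect_equal(A2$values, 2 * A$values)
  expect_error(usle(mk(1), mk(1), mk(1), mk(1),
                    sed_raster(matrix(1, 2, 2), 5)), "misaligned")
  expect_error(usle(mk(1), mk(-0.1), mk(1), mk(1), mk(1)), ">= 0")
})

test_that("parameter rasters apply the class rules", {
  soil <- sed_raster(matrix(2L, 2, 4), 5)   # Ochrept everywhere
  lu <- sed_raster(matrix(c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 1L), 2, 4), 5)
  params <- resolve_member_params(0.200, 0.10, 0.45, "increasing")
  pr <- build_param_rasters(soil, lu, params, "mean")
  expect_equal(pr$K$values[1, 1], 0.0245)
  codes <- landuse_codes()
  cv <- pr$C$values[match(codes, lu$values)]
  names(cv) <- names(codes)
  expect_equal(unname(cv["road"]), 1)
  expect_equal(unname(cv["water"]), 0)
  expect_equal(unname(cv["microdam"]), 0)
  fc <- linked_c(0.200, "increasing")$forest_c
  expect_equal(unname(cv["forest"]), fc)
  expect_equal(round(unname(cv["forest"]), 3), 0.082)
  # growing forest C is the pasture/forest mean
  expect_equal(unname(cv["growing_forest"]), (0.200 + fc) / 2)
  ev <- pr$E$values[match(codes, lu$values)]
  names(ev) <- names(codes)
  expect_equal(unname(ev["microdam"]), 1)
  expect_equal(unname(ev["eucalyptus"]), (0.10 + 0.45) / 2)
  bad <- sed_raster(matrix(9L, 2, 4), 5)
  expect_error(build_param_rasters(soil, bad, params), "unknown land-use")
})

test_that("a 1-D retention chain matches the closed form", {
  # cells 1..5 drain east; stream at cell 5; 10 Mg eroded in cell 1
  dem <- sed_raster(matrix(seq(5, 1), 1, 5), 5)
  fl <- d8_flow(dem, threshold = 1e9)
  fl$streams[1, 5] <- TRUE
  cell_ha <- 25 / 1e4
  A <- sed_raster(matrix(c(10 / cell_ha, 0, 0, 0, 0), 1, 5), 5)
  E <- sed_raster(matrix(c(0, 0.65, 0.65, 0.65, 0), 1, 5), 5)
  out <- route_sediment(A, E, fl)
  expect_equal(out$exported_total, 10 * 0.35^3, tolerance = 1e-12)
  expect_equal(out$retained_total, 10 - 10 * 0.35^3, tolerance = 1e-12)
  # deposition is credited where trapping happens, declining downstream
  expect_equal(out$upstream_retention$values[1, 2], 6.5, tolerance = 1e-12)
  expect_equal(out$upstream_retention$values[1, 3], 3.5 * 0.65,
               tolerance = 1e-12)
  # with no trapping everything is exported
  E0 <- sed_raster(matrix(0, 1, 5), 5)
  expect_equal(route_sediment(A, E0, fl)$exported_total, 10)
  expect_error(route_sediment(A, sed_raster(matrix(1.2, 1, 5), 5), fl),
               "\\[0, 1\\]")
})

test_that("routing equals naive path-product enumeration on random grids", {
  for (seed in 1:10) {
    set.seed(seed)
    nr <- sample(8:12, 1); nc <- sample(8:12, 1)
    fl <- d8_flow(fill_depressions(random_dem(nr, nc, seed + 500)),
                  threshold = sample(c(5, 10, 20), 1))
    A <- sed_raster(matrix(runif(nr * nc, 0, 50), nr, nc), 5)
    E <- sed_raster(matrix(runif(nr * nc, 0, 0.9), nr, nc), 5)
    out <- route_sediment(A, E, fl)
    oracle <- oracle_route(as.vector(A$values) * 25 / 1e4,
                           as.vector(E$values),
                           as.vector(fl$streams),
                           as.vector(fl$downstream))
    expect_equal(as.vector(out$export_map$values), oracle$export,
                 tolerance = 1e-12)
    expect_equal(as.vector(out$upstream_retention$values), oracle$retained,
                 tolerance = 1e-12)
  }
})

test_that("mass is conserved and export responds monotonically", {
  fl <- d8_flow(fill_depressions(random_dem(12, 12, 99)), threshold = 15)
  set.seed(1)
  A <- sed_raster(matrix(runif(144, 0, 40), 12, 12), 5)
  E <- sed_raster(matrix(runif(144, 0, 0.8), 12, 12), 5)
  out <- route_sediment(A, E, fl)
  expect_equal(out$exported_total + out$retained_total, out$total_mass,
               tolerance = 1e-12)
  # raising any single cell's E cannot increase export
  for (i in sample(which(!fl$streams), 10)) {
    E2 <- E; E2$values[i] <- min(1, E$values[i] + 0.2)
    expect_lte(route_sediment(A, E2, fl)$exported_total,
               out$exported_total + 1e-12)
  }
  # raising any single cell's soil loss cannot decrease export
  for (i in sample(144, 5)) {
    A2 <- A; A2$values[i] <- A$values[i] * 2
    expect_gte(route_sediment(A2, E, fl)$exported_total,
               out$exported_total - 1e-12)
  }
})

test_that("slope-binned totals partition the watershed budget", {
  b <- ref_bundle()
  params <- resolve_member_params(0.2, 0.1, 0.65, "increasing")
  out <- run_erosion_model(b, params, "mean")
  tab <- summarize_by_slope(out, b$slope, c(0, 15, 50))
  cell_ha <- b$dem$cell_size^2 / 1e4
  expect_equal(sum(tab$soil_loss_mg),
               sum(out$soil_loss$values, na.rm = TRUE) * cell_ha,
               tolerance = 1e-9)
  expect_equal(sum(tab$export_mg), out$exported_total, tolerance = 1e-9)
  expect_equal(sum(tab$retention_mg), out$retained_total, tolerance = 1e-9)
  # single catch-all bin reproduces the totals
  tab1 <- summarize_by_slope(out, b$slope, c(0, Inf))
  expect_equal(tab1$export_mg, out$exported_total, tolerance = 1e-9)
  # uniform slope lands in its own bin
  su <- sed_raster(matrix(20, nrow(b$slope$values), ncol(b$slope$values)), 5)
  tab2 <- summarize_by_slope(out, su, c(0, 15, 50))
  expect_equal(tab2$soil_loss_mg[1], 0)
  expect_equal(tab2$soil_loss_mg[2], sum(tab$soil_loss_mg), tolerance = 1e-9)
  expect_error(summarize_by_slope(out, b$slope, c(10, 5)), "unsorted")
})
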