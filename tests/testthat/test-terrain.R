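test_that("depression filling leaves draining surfaces alone and removes pits", {
  # monotone tilted plane already drains
  plane <- sed_raster(outer(1:10, 1:10, function(i, j) i + 0.5 * j), 5)
  expect_equal(fill_depressions(plane)$values, plane$values)

  # a single pit is raised to (at least) its lowest neighbour
  z <- outer(1:9, 1:9, function(i, j) i + 0.5 * j)
  z[5, 5] <- -10
  lowest_nb <- min(z[4:6, 4:6][-5])
  filled <- fill_depressions(sed_raster(z, 5))$values
  expect_gte(filled[5, 5], lowest_nb)
  expect_equal(filled[-5, ], z[-5, ], tolerance = 1e-12)

  # random surfaces come out pit-free (brute-force scan)
  for (seed in 1:5) {
    r <- random_dem(20, 20, seed)
    expect_length(find_pits(fill_depressions(r)$values), 0)
  }
  expect_error(fill_depressions(sed_raster(matrix(NA_real_, 4, 4), 5)),
               "nodata")
})

test_that("D8 directions and accumulation match forced geometry", {
  # plane tilted down to the east: everything flows east
  dem <- sed_raster(outer(1:8, 8:1, function(i, j) j * 1.0), 5)
  fl <- d8_flow(dem, threshold = 1e9)
  expect_true(all(fl$direction[, -8] == 1L))
  # accumulation grows along each row: column j drains j-1 cells
  for (j in 1:8) expect_true(all(fl$accumulation[, j] == j - 1))
  # conservation: off-grid-draining cells account for every cell
  sinks <- which(fl$direction == 0L)
  expect_equal(sum(fl$accumulation[sinks] + 1), 64)
})

test_that("D8 accumulation equals brute-force path enumeration", {
  for (seed in 1:20) {
    nr <- sample(6:15, 1); nc <- sample(6:15, 1)
    fl <- d8_flow(fill_depressions(random_dem(nr, nc, seed + 100)), 10)
    oracle <- oracle_accumulation(as.vector(fl$downstream),
                                  !is.na(as.vector(fl$direction)))
    expect_equal(as.vector(fl$accumulation), oracle)
  }
})

test_that("V-shaped valley accumulates along its axis", {
  # valley axis at column 5, draining south
  z <- outer(1:9, 1:9, function(i, j) (9 - i) * 0.5 + abs(j - 5) * 2)
  fl <- d8_flow(sed_raster(z, 5), threshold = 1e9)
  oracle <- oracle_accumulation(as.vector(fl$downstream),
                                rep(TRUE, 81))
  expect_equal(as.vector(fl$accumulation), oracle)
  # the outlet of the axis drains strictly more than any off-axis cell
  expect_equal(which.max(fl$accumulation), (5 - 1) * 9 + 9)
})

test_that("unresolvable interior flats are reported", {
  z <- outer(1:9, 1:9, function(i, j) pmax(abs(i - 5), abs(j - 5)))
  expect_error(d8_flow(sed_raster(z, 5)), "flat")
})

test_that("slope_percent reproduces analytic gradients", {
  g30 <- sed_raster(outer(1:12, 1:12, function(i, j) 0.30 * 5 * j), 5)
  s <- slope_percent(g30)$values
  expect_equal(s[2:11, 2:11], matrix(30, 10, 10), tolerance = 1e-10)
  flat <- sed_raster(matrix(2, 8, 8), 5)
  expect_equal(slope_percent(flat)$values, matrix(0, 8, 8))
  g34 <- sed_raster(outer(1:12, 1:12,
                          function(i, j) 0.3 * 5 * j + 0.4 * 5 * i), 5)
  expect_equal(slope_percent(g34)$values[2:11, 2:11], matrix(50, 10, 10),
               tolerance = 1e-10)
})

test_that("LS factor follows the two-dimensional slope-length form", {
  # single flow line: plane tilted east, slope 20%
  dem <- sed_raster(outer(1:5, 5:1, function(i, j) 0.20 * 5 * j), 5)
  fl <- d8_flow(dem, threshold = 1e9)
  slope <- slope_percent(dem)
  ls <- ls_factor(fl, slope)$values
  # independent hand evaluation on the interior (slope exactly 20%)
  D <- 5
  theta <- atan(0.20); st <- sin(theta)
  beta <- (st / 0.0896) / (3 * st^0.8 + 0.56)
  m <- beta / (1 + beta)
  S <- 16.8 * st - 0.5
  for (j in 2:4) {
    A <- (j - 1) * D^2
    L <- ((A + D^2)^(m + 1) - A^(m + 1)) / (D^(m + 2) * 22.13^m)
    expect_equal(ls[3, j], L * S, tolerance = 1e-10)
  }
  # flat terrain: minimum S factor, L = 1 at zero contributing area
  flat <- sed_raster(matrix(5, 6, 6), 5)
  flat$values <- flat$values + outer(1:6, 1:6, function(i, j) j * 1e-9)
  flf <- d8_flow(flat, 1e9)
  ls0 <- ls_factor(flf, slope_percent(sed_raster(matrix(5, 6, 6), 5)))$values
  expect_equal(ls0[3, 1], 0.03, tolerance = 1e-6)
  # monotone in slope at fixed contributing area
  s10 <- sed_raster(matrix(10, 2, 2), 5); s40 <- sed_raster(matrix(40, 2, 2), 5)
  fake_flow <- list(accumulation = matrix(4, 2, 2),
                    direction = matrix(1L, 2, 2), cell_size = 5)
  expect_true(all(ls_factor(fake_flow, s10)$values <
                  ls_factor(fake_flow, s40)$values))
  bad <- list(accumulation = matrix(-1, 2, 2), direction = matrix(1L, 2, 2),
              cell_size = 5)
  expect_error(ls_factor(bad, s10), "negative")
})

test_that("distance_to_stream is the exact Euclidean transform", {
  st <- matrix(FALSE, 7, 7); st[4, 4] <- TRUE
  d <- distance_to_stream(st, cell_size = 5)$values
  expect_equal(d[4, 4], 0)
  expect_equal(d[4, 5], 5)
  expect_equal(d[3, 3], sqrt(2) * 5)
  # random masks against brute force
  for (seed in 1:5) {
    set.seed(seed)
    st <- matrix(runif(15 * 11) < 0.1, 15, 11)
    if (!any(st)) st[3, 3] <- TRUE
    d <- distance_to_stream(st, cell_size = 2)$values
    cells <- which(st, arr.ind = TRUE)
    for (k in sample(15 * 11, 20)) {
      i <- ((k - 1) %% 15) + 1; j <- ((k - 1) %/% 15) + 1
      brute <- min(sqrt((cells[, 1] - i)^2 + (cells[, 2] - j)^2)) * 2
      expect_equal(d[i, j], brute, tolerance = 1e-12)
    }
  }
  expect_error(distance_to_stream(matrix(FALSE, 3, 3), 5), "empty")
})
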