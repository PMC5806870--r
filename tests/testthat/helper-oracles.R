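# Independent brute-force oracles. These deliberately share no code with
# the package internals they check.

# strict interior pit detector: cell lower than all its 8 neighbours
find_pits <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  pits <- c()
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    if (is.na(z[i, j])) next
    neigh <- c(z[i - 1, j - 1], z[i - 1, j], z[i - 1, j + 1],
               z[i, j - 1], z[i, j + 1],
               z[i + 1, j - 1], z[i + 1, j], z[i + 1, j + 1])
    if (all(z[i, j] < neigh, na.rm = TRUE) && !all(is.na(neigh)))
      pits <- c(pits, (j - 1) * nr + i)
  }
  pits
}

# path-following accumulation: for every cell, walk downstream and count
# the visit at every strictly downstream cell
oracle_accumulation <- function(dn, valid) {
  acc <- rep(0, length(dn))
  for (i in which(valid)) {
    j <- dn[i]
    steps <- 0
    while (!is.na(j)) {
      acc[j] <- acc[j] + 1
      j <- dn[j]
      steps <- steps + 1
      if (steps > length(dn)) stop("cycle detected in flow directions")
    }
  }
  acc
}

# per-source path-product sediment routing (naive enumeration)
oracle_route <- function(mass, E, streams, dn) {
  n <- length(mass)
  retained <- rep(0, n); export <- rep(0, n)
  for (i in seq_len(n)) {
    m <- mass[i]
    if (is.na(m) || m == 0) next
    if (isTRUE(streams[i])) { export[i] <- export[i] + m; next }
    cur <- i
    repeat {
      nxt <- dn[cur]
      if (is.na(nxt)) { export[cur] <- export[cur] + m; break }
      if (isTRUE(streams[nxt])) { export[nxt] <- export[nxt] + m; break }
      dep <- E[nxt] * m
      retained[nxt] <- retained[nxt] + dep
      m <- m - dep
      cur <- nxt
    }
  }
  list(retained = retained, export = export)
}

# random rough DEM raster for property tests
random_dem <- function(nr, nc, seed, cell = 5) {
  set.seed(seed)
  base <- outer(seq_len(nr), seq_len(nc), function(i, j) (nr - i) * 2 + j * 0.7)
  sed_raster(base + matrix(rnorm(nr * nc, sd = 2), nr, nc), cell)
}

# memoised mini reference bundle shared across test files
.bundle_cache <- new.env(parent = emptyenv())
ref_bundle <- function(seed = 1) {
  key <- paste0("b", seed)
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- make_reference_watershed(seed)
  .bundle_cache[[key]]
}
.ens_cache <- new.env(parent = emptyenv())
ref_ensemble <- function(seed = 1) {
  key <- paste0("e", seed)
  if (is.null(.ens_cache[[key]])) {
    b <- ref_bundle(seed)
    .ens_cache[[key]] <- run_ensemble(b, b$truth$observed_se)
  }
  .ens_cache[[key]]
}
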