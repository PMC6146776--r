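# Shared fixtures and independent oracles, all built in code.

# Flat-colour raster
flat_raster <- function(nr, nc, rgb, res = 454) {
  px <- array(0, c(nr, nc, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  section_raster(px, res)
}

# Paint a filled disc (by pixel-centre distance) into a logical matrix
paint_disc <- function(mask, cy, cx, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  ys <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
  sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  mask[ys, xs] <- mask[ys, xs] | sub
  mask
}

# Build a tile map directly from per-tile counts
toy_map <- function(tissue_px, droplet_px, tile_size_um = 32,
                    res = 1000, source_id = "toy") {
  n <- length(tissue_px)
  tiles <- data.frame(row = seq_len(n) - 1L, col = 0L,
                      tissue_px = as.integer(tissue_px),
                      droplet_px = as.integer(droplet_px))
  steatoscore:::new_tile_fraction_map(tiles, c(n, 1L), tile_size_um, res,
                                      source_id)
}

# Independent 8-connectivity component oracle: iterative flood fill
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[i] != 0) next
      lab[i] <- cur
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (mask[j] && lab[j] == 0L) stack <- c(stack, j)
        }
      }
    }
  }
  lab
}

# From-definitions one-way ANOVA ICC oracle (explicit loops)
icc_oracle <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g); N <- length(values)
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (gi in g) {
    ssb <- ssb + length(gi) * (mean(gi) - gm)^2
    for (v in gi) ssw <- ssw + (v - mean(gi))^2
  }
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  n0 <- (N - sum(vapply(g, length, 1)^2) / N) / (k - 1)
  vb <- max(0, (msb - msw) / n0)
  if (vb + msw > 0) vb / (vb + msw) else 0
}

# O(n^2) double-loop Kendall tau-b oracle
tau_b_oracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den > 0) (C - D) / den else NA_real_
}

# Small rendered section used by several tests (cached per session)
cached_section <- local({
  store <- new.env()
  function(seed = 5, target = 0.12, size = 640, pattern = "uniform",
           n_vessels = 0, n_cracks = 0, res = 454) {
    key <- paste(seed, target, size, pattern, n_vessels, n_cracks, res,
                 sep = "_")
    if (is.null(store[[key]])) {
      store[[key]] <- generate_section(section_spec(
        width_px = size, height_px = size, resolution_nm_per_px = res,
        target_area_fraction = target, pattern = pattern,
        n_vessels = n_vessels, n_cracks = n_cracks, seed = seed))
    }
    store[[key]]
  }
})
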