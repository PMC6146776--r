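# Pixel classification, tissue mask morphology, blob extraction and the
# droplet shape rule.

test_that("pixel classification follows HSV saturation/brightness thresholds", {
  cfg <- segmentation_config(saturation_max = 0.25, brightness_min = 0.8)
  # pure white: zero saturation, full brightness
  expect_true(all(classify_pixels(flat_raster(4, 4, c(255, 255, 255)), cfg)))
  # eosin pink (230,140,160): saturation (230-140)/230 = 0.391 > 0.25
  expect_false(any(classify_pixels(flat_raster(4, 4, c(230, 140, 160)), cfg)))
  # pure black: brightness 0 below threshold
  expect_false(any(classify_pixels(flat_raster(4, 4, c(0, 0, 0)), cfg)))
  # boundary case: bright pixel with saturation exactly at the threshold
  px <- c(240, 180, 180)  # saturation 60/240 = 0.25, brightness 0.94
  expect_true(all(classify_pixels(flat_raster(2, 2, px), cfg)))
  # same hue, slightly more saturated: excluded
  expect_false(any(classify_pixels(flat_raster(2, 2, c(240, 175, 175)), cfg)))
})

test_that("empty or malformed rasters are rejected", {
  expect_error(section_raster(array(0, c(0, 4, 3)), 454), "empty image")
  expect_error(section_raster(array(300, c(4, 4, 3)), 454), "255")
  expect_error(section_raster(array(0, c(4, 4, 3)), -1), "positive")
})

test_that("tissue mask fills droplets and keeps separated regions apart", {
  # resolution chosen so the 50 um closing radius is 4 px
  res <- 12500
  pink <- c(230, 140, 160)
  mk <- function(white_cols) {
    px <- array(0, c(50, 50, 3))
    for (ch in 1:3) px[, , ch] <- pink[ch]
    for (ch in 1:3) px[, white_cols, ch] <- 255
    section_raster(px, res)
  }
  # all-white raster: no tissue at all
  r_all <- flat_raster(50, 50, c(255, 255, 255), res)
  w <- classify_pixels(r_all)
  expect_equal(sum(compute_tissue_mask(r_all, w)), 0)

  # white gap of 10 px > 2 * closing radius: two components survive
  r2 <- mk(21:30)
  w2 <- classify_pixels(r2)
  t2 <- compute_tissue_mask(r2, w2)
  expect_equal(max(EBImage::bwlabel(t2 * 1L)), 2)
  expect_false(any(t2[, 25]))

  # narrow 3 px gap is closed into one component
  r1 <- mk(24:26)
  w1 <- classify_pixels(r1)
  t1 <- compute_tissue_mask(r1, w1)
  expect_equal(max(EBImage::bwlabel(t1 * 1L)), 1)

  # a white disc inside tissue is filled into the tissue mask
  pxd <- array(0, c(60, 60, 3))
  for (ch in 1:3) pxd[, , ch] <- pink[ch]
  disc <- paint_disc(matrix(FALSE, 60, 60), 30, 30, 8)
  for (ch in 1:3) { m <- pxd[, , ch]; m[disc] <- 255; pxd[, , ch] <- m }
  rd <- section_raster(pxd, res)
  td <- compute_tissue_mask(rd, classify_pixels(rd))
  expect_true(all(td[disc]))
})

test_that("blob extraction uses 8-connectivity and matches a flood-fill oracle", {
  tissue <- matrix(TRUE, 20, 20)
  # two discs touching diagonally at one corner form one blob
  m <- matrix(FALSE, 20, 20)
  m[3:6, 3:6] <- TRUE; m[7:10, 7:10] <- TRUE
  b <- extract_blobs(m, tissue, 454)
  expect_equal(nrow(b), 1)
  expect_equal(b$pixel_count, 32)

  # single 5x5 square
  m2 <- matrix(FALSE, 20, 20); m2[5:9, 5:9] <- TRUE
  b2 <- extract_blobs(m2, tissue, 454)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$pixel_count, 25)
  expect_equal(unname(unlist(b2[1, c("bbox_rmin", "bbox_rmax", "bbox_cmin", "bbox_cmax")])),
               c(5, 9, 5, 9))

  # empty mask
  expect_equal(nrow(extract_blobs(matrix(FALSE, 5, 5), matrix(TRUE, 5, 5), 454)), 0)

  # random masks: component count and sizes match the oracle
  set.seed(21)
  for (rep in 1:20) {
    m3 <- matrix(runif(400) < 0.35, 20, 20)
    lab <- flood_components(m3)
    b3 <- extract_blobs(m3, matrix(TRUE, 20, 20), 454)
    expect_equal(nrow(b3), max(lab))
    expect_equal(sort(b3$pixel_count), sort(as.vector(table(lab[lab > 0]))))
  }
})

test_that("blobs outside the tissue are discarded", {
  tissue <- matrix(FALSE, 20, 20); tissue[, 1:10] <- TRUE
  m <- matrix(FALSE, 20, 20)
  m[3:5, 3:5] <- TRUE        # inside tissue
  m[10:12, 15:17] <- TRUE    # outside
  b <- extract_blobs(m, tissue, 454)
  expect_equal(nrow(b), 1)
  expect_equal(b$pixel_count, 9)
})

test_that("disc circularity approaches 1 with radius and shapes sort correctly", {
  circ <- vapply(c(3, 6, 10, 16, 24, 30), function(r) {
    n <- 2 * r + 5
    m <- paint_disc(matrix(FALSE, n, n), (n + 1) / 2, (n + 1) / 2, r)
    extract_blobs(m, matrix(TRUE, n, n), 454)$circularity
  }, numeric(1))
  expect_true(all(circ > 0.8 & circ <= 1))
  expect_true(circ[6] > circ[1])
  expect_true(all(diff(circ) > -0.03))  # monotone up to discretization wiggle
  # a 1 px line is far from circular
  line <- matrix(FALSE, 10, 70); line[5, 5:64] <- TRUE
  bl <- extract_blobs(line, matrix(TRUE, 10, 70), 454)
  expect_lt(bl$circularity, 0.3)
})

test_that("droplet rule accepts droplet-scale discs and rejects vessels and cracks", {
  cfg <- segmentation_config()
  res <- 454
  mk_disc <- function(d_um) {
    r <- d_um * 1000 / res / 2
    n <- as.integer(2 * r + 8)
    m <- paint_disc(matrix(FALSE, n, n), (n + 1) / 2, (n + 1) / 2, r)
    extract_blobs(m, matrix(TRUE, n, n), res)
  }
  rule <- droplet_rule(cfg)
  expect_true(rule(mk_disc(15)))    # droplet-sized disc
  expect_false(rule(mk_disc(150)))  # vessel-scale disc above max diameter
  line <- matrix(FALSE, 10, 70); line[5, 5:64] <- TRUE
  expect_false(rule(extract_blobs(line, matrix(TRUE, 10, 70), res)))
})

test_that("classify_blobs builds the accepted-union mask and honours a custom predicate", {
  tissue <- matrix(TRUE, 40, 40)
  m <- paint_disc(matrix(FALSE, 40, 40), 12, 12, 8)
  m[30:31, 5:35] <- TRUE  # crack-like bar
  b <- extract_blobs(m, tissue, 1000)
  mask <- classify_blobs(b, tissue, segmentation_config())
  blobs <- attr(mask, "blobs")
  expect_equal(sum(blobs$accepted), 1)
  expect_true(all(mask[paint_disc(matrix(FALSE, 40, 40), 12, 12, 7)]))
  expect_false(any(mask[30:31, 5:35]))
  # droplet mask is a subset of white and tissue
  expect_true(all(!mask | (m & tissue)))
  # swap in an accept-everything classifier
  mask_all <- classify_blobs(b, tissue, predicate = function(bl) rep(TRUE, nrow(bl)))
  expect_equal(sum(mask_all), sum(m))
})

test_that("segmentation is deterministic and respects mask inclusion", {
  s <- cached_section(seed = 5, target = 0.12, size = 384)
  seg1 <- segment_section(s$raster)
  seg2 <- segment_section(s$raster)
  expect_identical(seg1$droplet, seg2$droplet)
  expect_true(all(!seg1$droplet | (seg1$white & seg1$tissue)))
})
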