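# Standard and focused score laws.

test_that("standard score is the tissue-area-weighted whole-section fraction", {
  m <- toy_map(c(100, 300), c(10, 0))
  expect_equal(standard_score(m)$value, 10 / 400)
  # equal-area half-steatotic tiles
  m2 <- toy_map(rep(100, 4), rep(50, 4))
  expect_equal(standard_score(m2)$value, 0.5)
  # tile-mean mode is the unweighted mean of tile fractions
  expect_equal(standard_score(m, mode = "tile-mean")$value, mean(c(0.1, 0)))
})

test_that("steatotic tile selection keeps positive-fraction tissue tiles", {
  m <- toy_map(rep(10, 4), c(0, 0, 2, 4))
  expect_equal(sort(steatotic_tiles(m)), c(0.2, 0.4))
  expect_equal(steatotic_tiles(toy_map(rep(10, 3), c(0, 0, 0))), numeric(0))
  expect_equal(length(steatotic_tiles(toy_map(rep(10, 3), c(1, 2, 3)))), 3)
})

test_that("focused mean restricts to steatotic tiles and obeys the min-tile rule", {
  m <- toy_map(rep(10, 4), c(0, 0, 2, 4))
  spec1 <- score_spec("focused", "mean", min_steatotic_tiles = 1)
  r <- focused_score(m, spec1)
  expect_equal(r$value, 0.3)
  expect_equal(r$n_tiles_steatotic, 2L)
  expect_equal(standard_score(m)$value, 0.15)  # the contrast the focus removes

  # 99 steatotic tiles with a minimum of 100: undefined
  m99 <- toy_map(rep(10, 99), rep(5, 99))
  expect_true(is.na(focused_score(m99, score_spec("focused", "mean"))$value))
  m100 <- toy_map(rep(10, 100), rep(5, 100))
  expect_equal(focused_score(m100, score_spec("focused", "mean"))$value, 0.5)

  # all tiles steatotic with equal areas: focused mean equals standard score
  ma <- toy_map(rep(10, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(focused_score(ma, spec1)$value, standard_score(ma)$value)

  # one whole-tissue steatotic tile: degenerate-limit agreement
  m1 <- toy_map(1000, 123)
  expect_equal(focused_score(m1, spec1)$value, standard_score(m1)$value)
})

test_that("percentile matches its interpolation formulae", {
  expect_equal(percentile(c(1, 2, 3), 50), 2)
  expect_equal(percentile(1:10, 70), 7.3)
  expect_equal(percentile(5, 30), 5)
  expect_error(percentile(numeric(0), 50), "empty")
  expect_error(percentile(1:3, 0), "0, 100")
  set.seed(41)
  for (rep in 1:50) {
    v <- rexp(sample(1:40, 1))
    p <- runif(1, 1, 99)
    expect_equal(percentile(v, p, "linear"),
                 unname(quantile(v, p / 100, type = 7)))
    expect_equal(percentile(v, p, "inverted_cdf"),
                 unname(quantile(v, p / 100, type = 1)))
  }
})

test_that("percentile is monotone in p and bounded by the extremes", {
  set.seed(42)
  for (rep in 1:10) {
    v <- rbeta(50, 1, 4)
    ps <- sort(runif(8, 1, 99))
    for (mode in c("linear", "inverted_cdf")) {
      q <- vapply(ps, function(p) percentile(v, p, mode), numeric(1))
      expect_true(all(diff(q) >= 0))
      expect_true(all(q >= min(v) & q <= max(v)))
    }
  }
})

test_that("focused mean dominates the standard score on equal-area tiles", {
  set.seed(43)
  spec <- score_spec("focused", "mean", min_steatotic_tiles = 1)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    d <- round(runif(n, 0, 100) * (runif(n) < 0.7))
    m <- toy_map(rep(100, n), d)
    if (!any(d > 0)) next
    f <- focused_score(m, spec)$value
    s <- standard_score(m)$value
    expect_gte(f, s)
    if (any(d == 0)) expect_gt(f, s) else expect_equal(f, s)
  }
})

test_that("focused scores ignore zero-fraction tiles while the standard score shifts", {
  set.seed(44)
  d <- c(rep(0, 10), round(runif(30, 1, 90)))
  m <- toy_map(rep(100, 40), d)
  m_ext <- toy_map(c(rep(100, 40), rep(100, 25)), c(d, rep(0, 25)))
  spec_m <- score_spec("focused", "mean", min_steatotic_tiles = 1)
  spec_p <- score_spec("focused", "percentile", percentile_p = 70,
                       min_steatotic_tiles = 1)
  expect_equal(focused_score(m, spec_m)$value, focused_score(m_ext, spec_m)$value)
  expect_equal(focused_score(m, spec_p)$value, focused_score(m_ext, spec_p)$value)
  expect_lt(standard_score(m_ext)$value, standard_score(m)$value)
})

test_that("exact standard score is identical across tile sizes on a section", {
  s <- cached_section(seed = 5, target = 0.12, size = 384)
  vals <- vapply(c(8, 16, 32, 64, 128), function(ts) {
    standard_score(compute_tile_map(s$droplet_mask, s$tissue_mask,
                                    s$raster$resolution_nm_per_px, ts))$value
  }, numeric(1))
  expect_true(all(abs(vals - vals[1]) < 1e-15))
  # On a millimetre-scale section (8 um tiles cover the tissue accurately)
  # the unweighted 8 um tile-mean agrees with the exact score to 1e-3.
  sm <- cached_section(seed = 5, target = 0.04, size = 1280, res = 1200)
  ex <- standard_score(compute_tile_map(sm$droplet_mask, sm$tissue_mask,
                                        1200, 32))$value
  m8 <- compute_tile_map(sm$droplet_mask, sm$tissue_mask, 1200, 8)
  expect_lt(abs(standard_score(m8, "tile-mean")$value - ex), 1e-3)
})

test_that("score JSON report carries the spec and null for undefined values", {
  m99 <- toy_map(rep(10, 99), rep(5, 99))
  j <- jsonlite::fromJSON(score_report_json(
    focused_score(m99, score_spec("focused", "mean"))))
  expect_null(j$value)
  expect_equal(j$n_tiles_steatotic, 99)
  j2 <- jsonlite::fromJSON(score_report_json(standard_score(m99)))
  expect_equal(j2$value, 0.5)
  expect_equal(j2$flavor, "standard")
})

test_that("score spec validation rejects inconsistent requests", {
  expect_error(score_spec("standard", "percentile", percentile_p = 50),
               "mean")
  expect_error(score_spec("focused", "percentile"), "percentile_p")
  expect_error(score_spec("focused", "percentile", percentile_p = 100),
               "percentile_p")
  expect_error(score_spec("focused", "mean", tile_size_um = 0), "positive")
})
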