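# ICC from one-way ANOVA components and Kendall tau-b.

test_that("icc_oneway reproduces hand-computed variance components", {
  # zero within-group variance, nonzero between: perfect reliability
  expect_equal(icc_oneway(c(1, 1, 1, 2, 2, 2), rep(c("A", "B"), each = 3))$icc, 1)
  # identical groups: clamped to zero
  expect_equal(icc_oneway(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))$icc, 0)
  # hand ANOVA: MSB=100, MSW=0.5, n0=2 -> var_between 49.75
  r <- icc_oneway(c(0, 1, 10, 11), rep(c("A", "B"), each = 2))
  expect_equal(r$ms_between, 100)
  expect_equal(r$ms_within, 0.5)
  expect_equal(r$n0, 2)
  expect_equal(r$var_between, 49.75)
  expect_equal(r$icc, 49.75 / 50.25)
  # constant data: both components zero, icc defined as 0
  expect_equal(icc_oneway(rep(3, 6), rep(c("A", "B"), each = 3))$icc, 0)
})

test_that("icc_oneway matches the from-definitions oracle on random instances", {
  set.seed(51)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    ni <- sample(2:7, k, replace = TRUE)
    g <- rep(seq_len(k), ni)
    v <- rnorm(k, sd = runif(1, 0, 3))[g] + rnorm(length(g))
    expect_lt(abs(icc_oneway(v, g)$icc - icc_oracle(v, g)), 1e-9)
  }
})

test_that("icc is invariant under shift and positive rescaling", {
  set.seed(52)
  g <- rep(1:4, each = 5)
  v <- rnorm(4, sd = 2)[g] + rnorm(20)
  base <- icc_oneway(v, g)$icc
  expect_equal(icc_oneway(v + 100, g)$icc, base)
  expect_equal(icc_oneway(v * 7.3, g)$icc, base)
})

test_that("icc_oneway rejects degenerate designs and excludes nothing silently", {
  expect_error(icc_oneway(1:3, c("A", "A", "B")), "at least 2 values")
  expect_error(icc_oneway(1:4, rep("A", 4)), "2 groups")
  expect_error(icc_oneway(c(1, NA, 2, 3), rep(c("A", "B"), each = 2)),
               "undefined")
})

test_that("icc estimator follows its exact F-distribution sampling law", {
  # At k=20 groups x n=20 the balanced one-way ICC estimate equals
  # max(0, F-1)/(F+n-1) with F ~ lambda * F(k-1, N-k); both its centre
  # (including the small high-ratio bias) and its sd (~0.06-0.09) must
  # match that law.
  set.seed(53)
  k <- 20; n <- 20
  for (ratio in c(0.2, 0.5, 0.8)) {
    est <- replicate(200, {
      g <- rep(seq_len(k), each = n)
      v <- rnorm(k, 0, sqrt(ratio))[g] + rnorm(k * n, 0, sqrt(1 - ratio))
      icc_oneway(v, g)$icc
    })
    lam <- 1 + n * ratio / (1 - ratio)
    f <- lam * rf(20000, k - 1, k * (n - 1))
    pred <- pmax(0, f - 1) / (f + n - 1)
    expect_lt(abs(mean(est) - mean(pred)), 0.02)
    expect_lt(abs(sd(est) - sd(pred)), 0.02)
  }
})

test_that("kendall tau-b handles perfect order, reversal and ties exactly", {
  expect_equal(kendall_tau_b(1:3, 1:3)$tau_b, 1)
  expect_equal(kendall_tau_b(1:3, 3:1)$tau_b, -1)
  r <- kendall_tau_b(c(1, 1, 2, 2), 1:4)
  expect_equal(r$concordant, 4)
  expect_equal(r$discordant, 0)
  expect_equal(r$ties_x, 2L)
  expect_equal(r$tau_b, 4 / sqrt(24))
  # all-tied x: undefined
  expect_true(is.na(kendall_tau_b(rep(1, 4), 1:4)$tau_b))
})

test_that("kendall tau-b matches both an enumeration oracle and stats::cor", {
  set.seed(54)
  for (rep in 1:40) {
    n <- sample(3:25, 1)
    x <- sample(1:5, n, replace = TRUE)   # heavy ties, like group covariates
    y <- round(rnorm(n), sample(0:2, 1))
    ours <- kendall_tau_b(x, y)$tau_b
    expect_equal(ours, tau_b_oracle(x, y))
    if (!is.na(ours))
      expect_equal(ours, unname(cor(x, y, method = "kendall")), tolerance = 1e-12)
  }
  # without ties tau-b reduces to (C - D) / n0
  x <- sample(100, 12); y <- sample(100, 12)
  r <- kendall_tau_b(x, y)
  expect_equal(r$tau_b, (r$concordant - r$discordant) / choose(12, 2))
})

test_that("evaluate_scores summarizes specs over a grouped design", {
  # two cohorts of toy maps at two tile sizes
  mk_image <- function(id, level) {
    maps <- lapply(c(16, 32), function(ts) {
      n <- 30
      d <- round(pmax(0, rnorm(n, level, 2)))
      toy_map(rep(100, n), pmin(d, 100), tile_size_um = ts, source_id = id)
    })
    names(maps) <- c("16", "32")
    maps
  }
  set.seed(55)
  ids <- sprintf("i%02d", 1:8)
  maps <- c(lapply(ids[1:4], mk_image, level = 5),
            lapply(ids[5:8], mk_image, level = 30))
  names(maps) <- ids
  design <- data.frame(source_id = ids,
                       group_label = rep(c("lo", "hi"), each = 4),
                       covariate = rep(c(1, 2), each = 4))
  specs <- list(score_spec("standard", "mean", tile_size_um = 16),
                score_spec("focused", "mean", tile_size_um = 32,
                           min_steatotic_tiles = 1))
  tab <- evaluate_scores(maps, design, specs)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("icc", "tau", "n_undefined", "flagged") %in% names(tab)))
  expect_true(all(tab$icc >= 0 & tab$icc <= 1))
  expect_true(all(tab$tau > 0))         # higher level => higher score
  expect_false(any(tab$flagged))
  expect_true(is.na(tab$tile_size_um[1]))

  # an unreachable min-tile rule flags the spec and omits its ICC
  specs2 <- list(score_spec("focused", "mean", tile_size_um = 32,
                            min_steatotic_tiles = 1000))
  expect_message(tab2 <- evaluate_scores(maps, design, specs2), "undefined")
  expect_true(tab2$flagged)
  expect_true(is.na(tab2$icc))
  expect_equal(tab2$n_undefined, 8)
})

test_that("groups can be ordered by mean standard score when no covariate exists", {
  set.seed(56)
  mk_image <- function(id, level) {
    n <- 25
    d <- round(pmax(0, rnorm(n, level, 1)))
    list("32" = toy_map(rep(100, n), pmin(d, 100), source_id = id))
  }
  ids <- sprintf("s%02d", 1:6)
  maps <- c(lapply(ids[1:3], mk_image, 3), lapply(ids[4:6], mk_image, 20))
  names(maps) <- ids
  design <- data.frame(source_id = ids, group_label = rep(c("g1", "g2"), each = 3))
  tab <- evaluate_scores(maps, design,
                         list(score_spec("focused", "mean",
                                         min_steatotic_tiles = 1)),
                         order_groups_by_standard = TRUE)
  expect_gt(tab$tau, 0.5)
})
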