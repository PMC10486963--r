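test_that("distance-band weights match hand-computed neighbourhoods", {
  two <- data.frame(cell_id = c("a", "b"), x_km = c(0, 10), y_km = 0)
  w <- build_weights(two, band_km = 15)
  expect_equal(w$S0, 2)
  expect_equal(w$W[1, 2], 1)

  three <- data.frame(cell_id = c("a", "b", "c"), x_km = c(0, 10, 20),
                      y_km = 0)
  w3 <- build_weights(three, band_km = 10)
  expect_equal(w3$S0, 4)            # (1,2) and (2,3), symmetric
  expect_equal(w3$W[1, 3], 0)

  expect_error(build_weights(lattice_cells(3, 3), band_km = 5), "island")
  wi <- build_weights(three, style = "inverse", band_km = 25)
  expect_equal(wi$W[1, 3], 1 / 20)
  wr <- build_weights(three, band_km = 10, row_standardize = TRUE)
  expect_equal(rowSums(wr$W), c(1, 1, 1), ignore_attr = TRUE)
  expect_error(build_weights(rbind(two, two[1, ])), "duplicate")
})

test_that("global Moran's I reproduces closed-form cases", {
  # alternating +/-1 on a 4-cell path: perfect negative autocorrelation
  path <- data.frame(cell_id = letters[1:4], x_km = c(0, 10, 20, 30),
                     y_km = 0)
  w <- build_weights(path, band_km = 10)
  m <- global_moran(c(1, -1, 1, -1), w)
  expect_equal(m$I, -1)
  # null expectation -1/(n-1)
  m11 <- global_moran(rnorm(11), build_weights(lattice_cells(11, 1),
                                               band_km = 15))
  expect_equal(m11$expected_I, -0.1)
  # a smooth gradient is positively autocorrelated
  cells <- lattice_cells(5, 5)
  mg <- global_moran(cells$x_km, build_weights(cells, band_km = 10))
  expect_gt(mg$I, 0)
  expect_error(global_moran(rep(2, 25), build_weights(cells, band_km = 10)),
               "constant")
})

test_that("Moran's I is location-scale invariant", {
  set.seed(14)
  cells <- lattice_cells(6, 6)
  w <- build_weights(cells, band_km = 15)
  for (i in 1:5) {
    x <- rnorm(36)
    expect_equal(global_moran(3 + 2.5 * x, w)$I, global_moran(x, w)$I)
  }
})

test_that("row-standardized Moran's I agrees with ape's implementation", {
  skip_if_not_installed("ape")
  set.seed(15)
  cells <- lattice_cells(7, 5)
  x <- rnorm(35)
  w <- build_weights(cells, band_km = 15, row_standardize = TRUE)
  ours <- global_moran(x, w)$I
  W <- matrix(0, 35, 35)
  d <- as.matrix(dist(cells[, c("x_km", "y_km")]))
  W[d > 0 & d <= 15] <- 1
  theirs <- ape::Moran.I(x, W)$observed   # ape row-standardizes internally
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the Monte-Carlo Moran test is deterministic and powerful", {
  cells <- lattice_cells(10, 10)
  w <- build_weights(cells, band_km = 20)
  set.seed(16)
  x <- rnorm(100)
  m1 <- moran_montecarlo(x, w, n_perm = 199, seed = 99)
  m2 <- moran_montecarlo(x, w, n_perm = 199, seed = 99)
  expect_identical(m1$p_value, m2$p_value)
  expect_identical(m1$permuted_I, m2$permuted_I)
  # a strongly autocorrelated field is detected at the permutation floor
  cfg <- synth_config(nx = 10, ny = 10, range_km = 30, sill = 1,
                      years = 2018, seed = 1)
  set.seed(17)
  f <- as.vector(simulate_latent_field(cfg, cells))
  mf <- moran_montecarlo(f, w, n_perm = 999, seed = 1)
  expect_equal(mf$p_value, 1 / 1000)
  # two-sided p is at most double the smaller tail and capped at 1
  mt <- moran_montecarlo(x, w, n_perm = 199, seed = 99,
                         alternative = "two.sided")
  expect_lte(mt$p_value, 1)
})

test_that("the correlogram reduces to global Moran on a single band", {
  set.seed(18)
  cells <- lattice_cells(6, 6)
  x <- rnorm(36)
  cg <- correlogram(x, cells, lag_edges_km = c(0, 15, 16), n_perm = 49,
                    seed = 1)
  expect_true(cg$empty[2])                 # no pair in (15, 16]
  g <- global_moran(x, build_weights(cells, band_km = 15))
  expect_equal(cg$I[1], g$I)
  expect_error(correlogram(x, cells, lag_edges_km = c(100, 150, 200),
                           n_perm = 9), "empty")
})

test_that("correlogram autocorrelation decays with distance on average", {
  cfg <- synth_config(nx = 15, ny = 15, range_km = 20, sill = 1,
                      years = 2018, seed = 1)
  cells <- lattice_cells(15, 15)
  set.seed(19)
  I1 <- I3 <- numeric(10)
  for (r in 1:10) {
    f <- as.vector(simulate_latent_field(cfg, cells))
    cg <- correlogram(f, cells, lag_edges_km = seq(0, 60, 15), n_perm = 9)
    I1[r] <- cg$I[1]; I3[r] <- cg$I[3]
  }
  expect_gt(mean(I1), mean(I3))
})

test_that("local Moran decomposes the global statistic exactly", {
  set.seed(20)
  cells <- lattice_cells(6, 5)
  w <- build_weights(cells, band_km = 15)
  for (i in 1:20) {
    x <- rnorm(30)
    l <- local_moran(x, w, n_perm = 9)
    expect_equal(sum(l$I_i), attr(l, "S0") * attr(l, "global_I"),
                 tolerance = 1e-10)
    expect_equal(attr(l, "global_I"), global_moran(x, w)$I)
  }
})

test_that("a lone spike is a High-Low outlier and islands stay NS", {
  cells <- rbind(lattice_cells(4, 4),
                 data.frame(cell_id = "far", x_km = 500, y_km = 500))
  w <- build_weights(cells, band_km = 15)
  expect_true(w$islands[17])
  x <- c(100, rep(0, 15), 3)
  l <- local_moran(x, w, n_perm = 199, seed = 1)
  expect_identical(l$quadrant[1], "HL")
  expect_equal(l$I_i[17], 0)
  expect_error(local_moran(rep(1, 17), w), "constant")
  cls <- classify_high_low(l)
  expect_identical(unname(cls[17]), "NS")
})

test_that("High/Low merging follows the quadrant + significance rule", {
  l <- structure(data.frame(
    cell_id = sprintf("c%d", 1:6),
    I_i = c(2, 1.5, -1, -0.8, 1.2, 0.1),
    z = c(1, 1, -1, 1, -1, 0.1), lag_z = c(1, -1, -1, -1, 1, 0.1),
    quadrant = c("HH", "HL", "LL", "HL", "LH", "HH"),
    p_value = c(0.01, 0.02, 0.01, 0.2, 0.03, 0.5),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)),
    class = c("lisa", "data.frame"))
  cls <- classify_high_low(l)
  expect_identical(unname(cls), c("High", "High", "Low", "NS", "Low", "NS"))
  # High and Low are disjoint and exhaustive with NS
  expect_identical(sum(cls == "High") + sum(cls == "Low") + sum(cls == "NS"),
                   6L)
})

test_that("class summaries report mean, SE, share and area", {
  counts <- c(6, 4, 1, 0, 2)
  classes <- c("High", "High", "Low", "NS", "NS")
  s <- lisa_class_summary(counts, classes)
  hi <- s[s$class == "High", ]
  expect_equal(hi$mean, 5)
  expect_equal(hi$se, sd(c(6, 4)) / sqrt(2))
  expect_equal(hi$share_pct, 100 * 10 / 13)
  expect_equal(hi$area_km2, 200)
})
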