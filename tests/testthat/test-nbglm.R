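make_frame <- function(n = 300, seed = 30, beta = c(0.2, 0.4, 0.4),
                       theta = 2, years = c(2008L, 2018L), rho = 0.8) {
  set.seed(seed)
  nx <- 20L
  cfg <- synth_config(nx = nx, ny = as.integer(n / nx), sill = 0,
                      beta = c(intercept = beta[1], COW = beta[2],
                               GF = beta[3]),
                      theta = theta, rho = rho, years = years, seed = seed)
  cov <- data.frame(cell_id = sprintf("c%04d", 1:n),
                    COW = rlnorm(n, log(500), 1),
                    GF = rlnorm(n, log(15), 1),
                    DEH = runif(n, 0, 40), SFS = rpois(n, 0.5),
                    WTG = rpois(n, 2))
  s <- simulate_census(cfg, cov)
  design_frame(s$census, cov, response_year = 2018, temporal_year = 2008)
}

test_that("the design frame standardizes and builds trend-surface terms", {
  fr <- make_frame()
  expect_identical(attr(fr, "temporal_term"), "NP08")
  for (v in c("COW", "GF", "NP08", "X", "Y")) {
    expect_equal(mean(fr[[v]]), 0, tolerance = 1e-10)
    expect_equal(sd(fr[[v]]), 1, tolerance = 1e-10)
  }
  expect_equal(fr$XY, fr$X * fr$Y)
  expect_equal(fr$X2Y, fr$X^2 * fr$Y)
  expect_equal(fr$Y3, fr$Y^3)
  # a Table-3-style term set: intercept + 2 covariates + NP + 2 spatial
  d <- build_design(fr, c("COW", "GF", "NP08", "Y", "Y2"))
  expect_identical(colnames(d$X),
                   c("(Intercept)", "COW", "GF", "NP08", "Y", "Y2"))
  expect_error(build_design(fr, "NOPE"), "unknown design term")
})

test_that("an intercept-only NB fit recovers log of the mean count", {
  fr <- make_frame(n = 200, seed = 31)
  f0 <- fit_nb_glm(character(0), fr)
  expect_equal(unname(coef(f0)[1]), log(mean(fr$y)), tolerance = 1e-6)
  expect_equal(f0$k, 2L)  # intercept + theta
  expect_equal(pseudo_r2(f0), 0, tolerance = 1e-12)
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "n > k")
  f <- fit_nb_glm("COW", make_frame(n = 200, seed = 32))
  expect_equal(f$aicc, aicc(f$loglik, f$k, f$n))
})

test_that("candidate enumeration counts and contents are exact", {
  specs <- enumerate_models(covariate_pool = c("COW", "GF"),
                            temporal_term = "NP08",
                            spatial_pool = "Y", max_spatial_terms = 1)
  expect_length(specs, 8)           # 2^2 covariate x 2 spatial subsets
  expect_true(any(vapply(specs, function(s) identical(s, "NP08"),
                         logical(1))))  # aspatial, covariate-free candidate
  # the published top-model term sets arise from the default pools
  specs_full <- enumerate_models(temporal_term = "NP08")
  key <- function(s) paste(sort(s), collapse = "+")
  have <- vapply(specs_full, key, character(1))
  for (row in list(c("COW", "GF", "NP08", "Y", "Y2"),
                   c("COW", "GF", "NP08", "X", "X2Y", "XY", "XY2"),
                   c("COW", "GF", "SFS", "NP08", "Y2", "Y3"),
                   c("COW", "DEH", "GF", "NP08", "Y", "Y2"),
                   c("COW", "GF", "NP08", "WTG", "Y", "Y2"),
                   c("COW", "GF", "NP08", "X", "X2", "XY", "XY2")))
    expect_true(key(row) %in% have)
  expect_error(enumerate_models(max_models = 10), "max_models")
})

test_that("likelihood never decreases along nested models", {
  fr <- make_frame(n = 300, seed = 33)
  ll <- c(fit_nb_glm(character(0), fr)$loglik,
          fit_nb_glm("COW", fr)$loglik,
          fit_nb_glm(c("COW", "GF"), fr)$loglik,
          fit_nb_glm(c("COW", "GF", "NP08"), fr)$loglik)
  expect_false(is.unsorted(ll))
})

test_that("pseudo-R2 grows with a real predictor and stays below 1", {
  fr <- make_frame(n = 500, seed = 34)
  f1 <- fit_nb_glm("NP08", fr)
  f2 <- fit_nb_glm(c("NP08", "COW"), fr)
  expect_gt(pseudo_r2(f2), pseudo_r2(f1))
  expect_lt(pseudo_r2(f2), 1)
  # alternative flavours are finite and rank the same way
  expect_gt(pseudo_r2(f2, "mcfadden"), pseudo_r2(f1, "mcfadden"))
  expect_gt(pseudo_r2(f2, "nagelkerke"), pseudo_r2(f1, "nagelkerke"))
})

test_that("ranking, deltas and Akaike weights match a by-hand recomputation", {
  fr <- make_frame(n = 300, seed = 35)
  fits <- fit_candidates(list(c("COW", "GF", "NP08"), c("COW", "NP08"),
                              "NP08"), fr)
  sel <- select_and_average(fits)
  ai <- sort(vapply(fits, function(f) f$aicc, numeric(1)))
  expect_equal(sel$table$AICc, ai)
  expect_equal(sel$table$delta, ai - min(ai))
  w <- exp(-(ai - min(ai)) / 2)
  expect_equal(sel$table$weight, w / sum(w))
  expect_equal(sum(sel$table$weight), 1)
  expect_identical(sel$table$averaged, sel$table$delta < 2)
})

test_that("model averaging handles the degenerate and symmetric cases", {
  fr <- make_frame(n = 300, seed = 36)
  f1 <- fit_nb_glm(c("COW", "NP08"), fr)
  sel1 <- select_and_average(list(f1))
  expect_equal(sel1$table$weight, 1)
  expect_equal(sel1$coef_full, coef(f1))
  # two copies of one model: weights 1/2 each, average = the coefficients
  sel2 <- select_and_average(list(f1, f1))
  expect_equal(sel2$table$weight, c(0.5, 0.5))
  expect_equal(sel2$coef_full, coef(f1))
  # full averaging zero-fills absent terms; conditional does not
  f2 <- fit_nb_glm("NP08", fr)
  sel3 <- select_and_average(list(f1, f2), delta_threshold = Inf)
  w <- sel3$table$weight
  cow_models <- grepl("COW", sel3$table$model)
  expect_equal(sel3$coef_full[["COW"]], sum(w[cow_models]) *
                 sel3$coef_conditional[["COW"]])
})
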