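test_that("WSSR values reproduce hand-computed toy examples", {
  # one site, two points: C_exp = (0.5, 1.0), C_sim = (0.25, 1.0)
  sim <- data.frame(time_min = c(1, 2), y394 = c(0.25, 1.0),
                    y505 = c(1, 1))
  dat <- data.frame(time_min = c(1, 2), y394 = c(0.5, 1.0),
                    y505 = c(1, 1))
  b <- wssr_quant(sim, dat)
  expect_equal(b$wssr_y394, 0.25)          # [(1/0.5)(0.5-0.25)]^2
  expect_equal(b$wssr_y505, 0)
  # two sites + difference term, hand arithmetic:
  #   y394: (0.1/0.5)^2 + (0.1/1)^2            = 0.05
  #   y505: (0.05/0.25)^2 + (0.05/0.5)^2       = 0.05
  #   diff: dexp = (0.25, 0.5), dsim = (0.10, 0.45)
  #         (0.15/0.25)^2 + (0.05/0.5)^2       = 0.37
  b <- wssr_hybr(toy_sim(), toy_data())
  expect_equal(b$wssr_y394, 0.05)
  expect_equal(b$wssr_y505, 0.05)
  expect_equal(b$wssr_quant, 0.10)
  expect_equal(b$wssr_diff, 0.37)
  expect_equal(b$wssr_hybr, 0.47)
})

test_that("perfect fits score zero and residual scaling is quadratic", {
  d <- toy_data()
  expect_equal(wssr_hybr(as.data.frame(d), d)$wssr_hybr, 0)
  base <- wssr_hybr(toy_sim(), toy_data())
  doubled <- toy_data()
  s <- toy_sim()
  s$y394 <- doubled$y394 - 2 * (doubled$y394 - s$y394)
  s$y505 <- doubled$y505 - 2 * (doubled$y505 - s$y505)
  expect_equal(wssr_hybr(s, doubled)$wssr_quant, 4 * base$wssr_quant)
})

test_that("hybrid WSSR never drops below the quantitative WSSR", {
  set.seed(10)
  for (i in 1:20) {
    sim <- toy_sim()
    sim$y394 <- sim$y394 * stats::runif(2, 0.5, 1.5)
    sim$y505 <- sim$y505 * stats::runif(2, 0.5, 1.5)
    b <- wssr_hybr(sim, toy_data())
    expect_gte(b$wssr_hybr, b$wssr_quant)
    expect_gte(b$wssr_quant, 0)
  }
})

test_that("zero-valued and near-degenerate points are excluded, not infinite", {
  dat <- structure(data.frame(time_min = c(0, 1), y394 = c(0, 1),
                              y505 = c(0, 1)),
                   class = c("lck_dataset", "data.frame"))
  sim <- data.frame(time_min = c(0, 1), y394 = c(0.2, 1), y505 = c(0.1, 1))
  b <- wssr_hybr(sim, dat)
  expect_true(is.finite(b$wssr_hybr))
  expect_equal(b$wssr_quant, 0)   # the t=0 points carry no weight
  expect_equal(b$wssr_diff, 0)    # |dexp| = 0 at both points
  # raising the exclusion floor drops small-separation points from the
  # difference term only
  d2 <- toy_data()
  b_lo <- wssr_hybr(toy_sim(), d2, diff_eps = 1e-6)
  b_hi <- wssr_hybr(toy_sim(), d2, diff_eps = 0.3)
  expect_equal(b_hi$wssr_quant, b_lo$wssr_quant)
  expect_lt(b_hi$wssr_diff, b_lo$wssr_diff)
})

test_that("mismatched time grids are an error", {
  sim <- toy_sim(); sim$time_min <- c(1, 3)
  expect_error(wssr_quant(sim, toy_data()), "time grids")
})

test_that("objective closures handle failures with the penalty value", {
  truth <- median_params()
  datasets <- generate_datasets(truth, lck_conditions()[1], noise_cv = 0)
  obj <- make_objective(datasets, "quant", truth, c("k_on", "k_cat_1"))
  x0 <- log10(unclass(truth)[c("k_on", "k_cat_1")])
  expect_lt(obj(x0), 1e-8)
  # absurd rates that break the integrator come back as the penalty, and
  # the residual closure returns a flat finite vector
  rfn <- lckautoreg:::make_residual_fn(datasets, truth,
                                       c("k_on", "k_cat_1"))
  expect_true(all(is.finite(rfn(c(300, 300)))))
})
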