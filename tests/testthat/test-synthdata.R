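high <- lck_conditions()$high_lck

test_that("zero-noise datasets equal the renormalized simulation", {
  d <- generate_dataset(median_params(), high, noise_cv = 0)
  obs <- observables(simulate_lck(median_params(), high,
                                  times = default_time_grid() * 60),
                    normalization = "site90")
  i <- match(default_time_grid() * 60, obs$time_s)
  expect_equal(d$y394, obs$y394[i], tolerance = 1e-9)
  expect_equal(d$y505, obs$y505[i], tolerance = 1e-9)
  expect_equal(d$y394[d$time_min == 90], 1)
})

test_that("datasets are reproducible by seed and t=0 stays zero", {
  d1 <- generate_dataset(median_params(), high, seed = 3)
  d2 <- generate_dataset(median_params(), high, seed = 3)
  d3 <- generate_dataset(median_params(), high, seed = 4)
  expect_identical(d1$y394, d2$y394)
  expect_false(identical(d1$y394, d3$y394))
  expect_equal(d1$y394[d1$time_min == 0], 0)
  expect_equal(d1$y505[d1$time_min == 0], 0)
})

test_that("replicate noise matches the lognormal model by Monte Carlo", {
  # After renormalization by the noisy 90-min value, a mid-curve point is a
  # ratio of two independent lognormal factors: its CV is sqrt(2)*cv (the
  # Monte-Carlo oracle for the pipeline), while the injected per-point
  # factor itself has CV = cv.
  cv <- 0.1
  grid <- c(0, 30, 90)
  vals <- replicate(500, {
    d <- generate_dataset(median_params(), high, times_min = grid,
                          noise_cv = cv)
    d$y394[2]
  })
  emp_cv <- stats::sd(vals) / mean(vals)
  expect_lt(abs(emp_cv - sqrt(2) * cv), 0.15 * sqrt(2) * cv)
  # injected single-point factor: reconstruct against the noiseless curve
  d0 <- generate_dataset(median_params(), high, times_min = grid,
                         noise_cv = 0)
  ratio <- vals / d0$y394[2]          # = eps_i / eps_90
  sdlog <- stats::sd(log(ratio))
  expect_lt(abs(sdlog / sqrt(2) - sqrt(log(1 + cv^2))), 0.15 * cv)
})

test_that("generated datasets keep the published phospho-site orderings", {
  sets <- generate_datasets(median_params(), noise_cv = 0)
  mid <- function(d) d$time_min %in% c(15, 30, 45, 60)
  for (nm in c("high_lck", "high_lck_csk", "low_lck")) {
    d <- sets[[nm]]
    expect_true(all(d$y394[mid(d)] > d$y505[mid(d)]), info = nm)
  }
  d <- sets$low_lck_csk
  expect_true(all(d$y505[mid(d)] > d$y394[mid(d)]))
})

test_that("dataset CSV round trip is lossless", {
  d <- generate_dataset(median_params(), high, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- load_dataset(path, cond = high)
  expect_equal(d2$time_min, d$time_min, tolerance = 1e-12)
  expect_equal(d2$y394, d$y394, tolerance = 1e-12)
  expect_equal(d2$y505, d$y505, tolerance = 1e-12)
  expect_equal(attr(d2, "condition_label"), "high_lck")
  expect_equal(nrow(d2), length(default_time_grid()))
})

test_that("malformed dataset files are rejected with row diagnostics", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("time_min,y394,y505", "0,0,0", "-5,0.5,0.4", "10,0.7,0.6"),
             path)
  expect_error(load_dataset(path), "negative/missing time: \\[2\\]")
  writeLines(c("time_min,y394,y505", "0,0,0", "10,0.7,0.6", "10,0.8,0.6"),
             path)
  expect_error(load_dataset(path), "duplicated time: \\[3\\]")
  writeLines(c("time_min,y394,y505", "0,0,0"), path)
  expect_error(load_dataset(path), "at least 2")
})
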