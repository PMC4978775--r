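conds <- lck_conditions()

test_that("no catalysis means no phosphorylation anywhere", {
  th <- unclass(median_params())
  th[startsWith(names(th), "k_cat")] <- 0
  traj <- simulate_lck(rate_params(th), conds$high_lck_csk)
  obs <- observables(traj, normalization = "total_lck")
  expect_true(all(abs(obs$y394) < 1e-9))   # integrator noise only
  expect_true(all(abs(obs$y505) < 1e-9))
  expect_lt(fraction_pp(traj, 5400), 1e-9)
})

test_that("total LCK and CSK are conserved along trajectories", {
  for (nm in c("high_lck_csk", "low_lck_csk", "validation")) {
    traj <- simulate_lck(median_params(), conds[[nm]])
    tot <- lckautoreg:::totals(traj)
    expect_lt(max(abs(tot$lck - tot$lck[1])) / tot$lck[1], 1e-6)
    if (tot$csk[1] > 0)
      expect_lt(max(abs(tot$csk - tot$csk[1])) / tot$csk[1], 1e-6)
  }
})

test_that("median rates doubly phosphorylate >= 90% of LCK by 90 min", {
  traj <- simulate_lck(median_params(), conds$high_lck)
  expect_equal(fraction_pp(traj, 0), 0)
  expect_gte(fraction_pp(traj, 5400), 0.90)
})

test_that("phospho-site order matches the experiments condition by condition", {
  obs <- lapply(conds[1:4], function(cc)
    observables(simulate_lck(median_params(), cc)))
  late <- function(o) o$time_s > 0
  # Y394 leads Y505 throughout in high LCK (+/- CSK) and low LCK
  for (nm in c("high_lck", "high_lck_csk", "low_lck"))
    expect_true(all(obs[[nm]]$y394[late(obs[[nm]])] >
                      obs[[nm]]$y505[late(obs[[nm]])]), info = nm)
  # order reversed at 90 min in low LCK + CSK
  o <- obs$low_lck_csk
  i90 <- which.min(abs(o$time_s - 5400))
  expect_gt(o$y505[i90], o$y394[i90])
})

test_that("the Y394 burst is biphasic in the high-LCK conditions", {
  for (nm in c("high_lck", "high_lck_csk")) {
    o <- observables(simulate_lck(median_params(), conds[[nm]]))
    y60 <- stats::approx(o$time_s, o$y394, 60)$y
    i90 <- which.min(abs(o$time_s - 5400))
    expect_gte(y60, 0.5 * o$y394[i90])
  }
})

test_that("site90 normalization anchors both sites to 1 at 90 min", {
  o <- observables(simulate_lck(median_params(), conds$low_lck_csk),
                   normalization = "site90")
  i90 <- which.min(abs(o$time_s - 5400))
  expect_equal(o$y394[i90], 1)
  expect_equal(o$y505[i90], 1)
})

test_that("species fractions partition into free + bound = total", {
  o <- observables(simulate_lck(median_params(), conds$high_lck_csk))
  fr <- attr(o, "species_fractions")
  expect_equal(fr[, , "free"] + fr[, , "bound"], fr[, , "total"],
               tolerance = 1e-9)
  # total over the four forms accounts for all LCK
  expect_equal(unname(rowSums(fr[, , "total"])), rep(1, dim(fr)[1]),
               tolerance = 1e-6)
})

test_that("tightening integrator tolerances leaves observables unchanged", {
  times <- c(0, 60, 600, 5400)
  o1 <- observables(simulate_lck(median_params(), conds$high_lck_csk,
                                 times = times))
  o2 <- observables(simulate_lck(median_params(), conds$high_lck_csk,
                                 times = times, rtol = 1e-9, atol = 1e-13))
  expect_lt(max(abs(o1$y394 - o2$y394), abs(o1$y505 - o2$y505)), 1e-4)
})

test_that("validation condition phosphorylates dead LCK too", {
  traj <- simulate_lck(median_params(), conds$validation)
  expect_equal(nrow(traj$network$species), 73)
  dead_pp <- traj$densities[nrow(traj$densities), "Ld_PP"]
  expect_gt(dead_pp, 0)
  # fully doubly phosphorylated endpoint counts free and bound, dead and
  # active alike
  expect_lte(fraction_pp(traj, 5400), 1 + 1e-9)
})

test_that("median curve stays within a near-optimum ensemble's 50% band", {
  times <- c(0, 60 * c(1, 5, 15, 30, 60, 90))
  set.seed(42)
  curves <- NULL
  base <- log10_median <- log10(unclass(median_params()))
  for (r in 1:20) {
    th <- rate_params(stats::setNames(10^(base +
      stats::runif(38, -0.25, 0.25)), param_names()))
    o <- observables(simulate_lck(th, conds$high_lck, times = times))
    curves <- rbind(curves, c(o$y394, o$y505))
  }
  o <- observables(simulate_lck(median_params(), conds$high_lck,
                                times = times))
  med_curve <- c(o$y394, o$y505)
  q25 <- apply(curves, 2, stats::quantile, 0.25)
  q75 <- apply(curves, 2, stats::quantile, 0.75)
  inside <- med_curve >= q25 - 0.02 & med_curve <= q75 + 0.02
  expect_true(all(inside))
})

test_that("conditions with CSK require a CSK-bearing network", {
  net <- lck_network(csk = "none")
  expect_error(simulate_lck(median_params(), conds$high_lck_csk,
                            network = net),
               "excludes")
})
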