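test_that("selection filter logic matches a brute-force oracle", {
  set.seed(20)
  n <- 100
  train <- 10^stats::runif(n, -1, 3)
  val <- 10^stats::runif(n, -1, 2)
  pp <- stats::runif(n)
  got <- apply_selection(train, val, pp, 7.1, 3.3, 0.9)
  oracle <- vapply(seq_len(n), function(i) {
    if (train[i] >= 7.1) "training"
    else if (val[i] >= 3.3) "validation"
    else if (pp[i] < 0.9) "double_phospho"
    else "none"
  }, character(1))
  expect_identical(got, oracle)
  # canonical pass-through example
  expect_identical(apply_selection(6.0, 2.0, 0.95, 7.1, 3.3, 0.9), "none")
  # all failing criterion 1 are attributed there
  expect_true(all(apply_selection(rep(10, 5), rep(0.1, 5), rep(1, 5),
                                  7.1, 3.3, 0.9) == "training"))
  # idempotence: re-filtering the survivors removes nothing
  keep <- got == "none"
  expect_true(all(apply_selection(train[keep], val[keep], pp[keep],
                                  7.1, 3.3, 0.9) == "none"))
})

test_that("full selection retains good sets and audits removals", {
  truth <- median_params()
  vdata <- generate_dataset(truth, lck_conditions()$validation,
                            noise_cv = 0.05, seed = 21)
  good <- unclass(truth)
  bad <- good; bad["k_cat_1"] <- 1e-15; bad["k_cat_13"] <- 1e-15
  pm <- rbind(good, good * 10^0.05, bad)
  colnames(pm) <- param_names()
  ens <- synthetic_ensemble(pm, wssr_quant = c(0.5, 1.0, 50))
  sel <- select_ensemble(ens, vdata)
  expect_equal(sel$audit$removed_by[3], "training")
  expect_equal(sel$audit$removed_by[1], "none")
  expect_lt(sel$audit$validation_wssr[1], 3.3)
  expect_gte(sel$audit$pp_fraction[1], 0.9)
  expect_equal(nrow(sel$ensemble$params), sum(sel$audit$removed_by == "none"))
  # re-running selection on the survivors is a no-op
  sel2 <- select_ensemble(sel$ensemble, vdata)
  expect_equal(nrow(sel2$ensemble$params), nrow(sel$ensemble$params))
})

test_that("elbow cutoff lands after the low-WSSR step", {
  wssr <- c(1, 1.2, 1.5, 2, 900, 1000, 1100, 1500)
  cut <- lckautoreg:::elbow_cutoff(wssr)
  expect_gt(cut, 2)
  expect_lte(cut, 900)
})

test_that("k-means with silhouette selection separates known blobs", {
  set.seed(22)
  n <- 15
  blob <- function(center) {
    m <- matrix(10^(center + stats::rnorm(n * 38, 0, 0.05)), n, 38)
    colnames(m) <- param_names()
    m
  }
  pm <- rbind(blob(-3), blob(3))
  cl <- cluster_parameter_sets(pm, k_candidates = 2:6, seed = 1)
  expect_equal(cl$k, 2)
  lab <- cl$labels
  expect_true(all(lab[1:n] == lab[1]) && all(lab[n + 1:n] == lab[n + 1]) &&
                lab[1] != lab[n + 1])
  cl2 <- cluster_parameter_sets(pm, k_candidates = 2:6, seed = 1)
  expect_identical(cl$labels, cl2$labels)
})

test_that("degenerate clustering input reports a single cluster", {
  pm <- matrix(1, 8, 38, dimnames = list(NULL, param_names()))
  cl <- cluster_parameter_sets(pm)
  expect_equal(cl$k, 1L)
  expect_true(all(cl$labels == 1))
  expect_match(cl$diagnostic, "degenerate")
})

test_that("ensemble statistics: CIs, degenerate case and enzyme ANOVA", {
  pm0 <- matrix(rep(unclass(median_params()), each = 5), 5, 38,
                dimnames = list(NULL, param_names()))
  st0 <- ensemble_stats(pm0)
  expect_equal(st0$summary$ci_lo, st0$summary$ci_hi)
  expect_equal(st0$summary$median, unname(unclass(median_params())))
  # identical sets: no sampling variability, no significance claims
  expect_true(all(is.na(st0$anova$p_value)))
  # enzyme-dependent shift on one substrate site -> significant ANOVA
  set.seed(23)
  pm <- matrix(10^stats::rnorm(20 * 38, 0, 0.1), 20, 38,
               dimnames = list(NULL, param_names()))
  # substrate Y394 on UU is phosphorylated by pairs 1, 4, 7, 13
  pm[, "k_cat_1"] <- 10^stats::rnorm(20, 4, 0.1)
  pm[, "k_cat_4"] <- 10^stats::rnorm(20, -4, 0.1)
  st <- ensemble_stats(pm)
  p_site <- st$anova$p_value[st$anova$substrate == "Y394 on UU" &
                               st$anova$rate == "kcat"]
  expect_lt(p_site, 0.01)
  expect_true(all(st$summary$ci_lo <= st$summary$median + 1e-12))
})
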