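test_that("active-only network has the published combinatorics", {
  net <- lck_network()
  expect_equal(nrow(net$species), 23)
  expect_equal(sum(net$species$kind == "free_lck"), 4)
  expect_equal(sum(net$species$kind == "free_csk"), 1)
  expect_equal(sum(net$species$kind == "lck_lck_dimer"), 16)
  expect_equal(sum(net$species$kind == "csk_lck_dimer"), 2)
  expect_equal(nrow(net$reactions), 54)
  expect_equal(sum(net$reactions$type == "association"), 18)
  expect_equal(sum(net$reactions$type == "dissociation"), 18)
  expect_equal(sum(net$reactions$type == "catalysis"), 18)
  # 38 kinetic parameters; 17 LCK binding parameters (1 shared k_on + 16
  # k_off)
  expect_length(param_names(), 38)
  p <- lck_pairs()
  expect_equal(1 + sum(p$enzyme != "CSK"), 17)
})

test_that("pair table covers every enzyme form and substrate site 4x", {
  p <- lck_pairs()
  lck <- p[p$enzyme != "CSK", ]
  expect_equal(nrow(lck), 16)
  expect_equal(as.vector(table(lck$enzyme)), rep(4L, 4))
  expect_equal(as.vector(table(paste(lck$site, lck$sub_form))), rep(4L, 4))
  # CSK phosphorylates Y505 only, on the two forms with Y505 free
  csk <- p[p$enzyme == "CSK", ]
  expect_equal(csk$site, c("Y505", "Y505"))
  expect_setequal(csk$sub_form, c("UU", "PU"))
})

test_that("two-form sub-model dimer counts match the brute-force oracle", {
  forms <- c("UU", "PU", "UP", "PP")
  for (a in forms) for (b in forms)
    expect_equal(count_pair_dimers(a, b), oracle_pair_dimers(a, b),
                 info = paste(a, b))
  # the representative hetero-pair supports exactly three dimers
  expect_equal(count_pair_dimers("UU", "PU"), 3)
})

test_that("dead-LCK variants yield the documented species counts", {
  expect_equal(nrow(enumerate_species(TRUE, "binder", "full")), 77)
  expect_equal(nrow(enumerate_species(TRUE, "binder", "species_only")), 73)
  expect_equal(nrow(enumerate_species(TRUE, "substrate_only", "full")), 45)
})

test_that("dead enzymes bind like active ones but never catalyze", {
  net <- lck_network(include_dead = TRUE, csk = "species_only")
  rx <- net$reactions
  dead_enz <- net$species$enz_dead[rx$r1] &
    net$species$kind[rx$r1] == "lck_lck_dimer"
  expect_true(all(rx$rate_factor[rx$type == "catalysis" & dead_enz] == 0))
  expect_true(all(rx$rate_factor[rx$type != "catalysis"] == 1))
  # dead dimer shares its pair's k_off name with the active counterpart
  for (pr in unique(rx$pair)) {
    koffs <- unique(rx$rate_name[rx$pair == pr & rx$type == "dissociation"])
    expect_length(koffs, 1)
  }
})

test_that("network generation is deterministic", {
  n1 <- lck_network()
  n2 <- lck_network()
  expect_identical(n1$species, n2$species)
  expect_identical(n1$reactions, n2$reactions)
  expect_identical(n1$stoich, n2$stoich)
})

test_that("stoichiometry conserves total LCK and CSK exactly", {
  for (net in list(lck_network(),
                   lck_network(TRUE, "binder", "species_only"),
                   lck_network(TRUE, "substrate_only", "full"))) {
    expect_equal(max(abs(crossprod(net$stoich, net$conservation$lck))), 0)
    expect_equal(max(abs(crossprod(net$stoich, net$conservation$csk))), 0)
  }
})

test_that("catalysis releases the substrate phosphorylated at the bound site", {
  net <- lck_network()
  rx <- net$reactions
  # enzyme U394U505 on Y394 of U394U505 yields free UU + free PU
  d <- which(net$species$id == "L_UU:L_UU.Y394")
  cat_rx <- rx[rx$type == "catalysis" & rx$r1 == d, ]
  expect_setequal(net$species$id[c(cat_rx$p1, cat_rx$p2)],
                  c("L_UU", "L_PU"))
  # no reaction consumes a doubly phosphorylated substrate site
  expect_false(any(net$species$id[rx$r2[rx$type == "association"]] == "L_PP"))
})

test_that("unknown species kinds are rejected", {
  sp <- enumerate_species()
  sp$kind[1] <- "mystery"
  expect_error(enumerate_reactions(sp), "unknown species kind")
})

test_that("CI table flags the internally inconsistent printed rows", {
  flags <- params_ci_flags()
  expect_setequal(flags$parameter,
                  c("k_off_1", "k_off_7", "k_off_8", "k_off_11",
                    "k_cat_7", "k_cat_csk_uu"))
})
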