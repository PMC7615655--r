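test_that("all built-in presets validate cleanly", {
  for (p in c("glycolysis", "oxidative_tca", "reductive_branch",
              "bifurcated_tca", "ppp_shunt")) {
    v <- validate_topology(build_topology(p))
    expect_identical(nrow(v), 0L, info = p)
  }
})

test_that("preset contents match their architecture", {
  ox <- build_topology("oxidative_tca", include_sdh = TRUE)
  expect_true("SDH" %in% names(ox$reactions))
  sdh <- get_reaction(ox, "SDH")
  expect_identical(sdh$substrates, "SUC")
  expect_identical(sdh$products, "FUM")
  expect_false("SDH" %in%
                 names(build_topology("bifurcated_tca")$reactions))
  trunc <- build_topology("oxidative_tca", include_sdh = FALSE)
  expect_false(any(c("SDH", "FH", "MDH") %in% names(trunc$reactions)))
  red <- build_topology("reductive_branch",
                        include_fumarate_reductase = FALSE)
  expect_false("FRD" %in% names(red$reactions))
  # recycling disabled: the only CO2_IN draws 100% unlabeled carbon
  bif0 <- build_topology("bifurcated_tca", recycle_fraction = 0)
  expect_identical(bif0$co2_policy$recycle_fraction, 0)
})

test_that("carbon is conserved in every preset reaction", {
  for (p in c("glycolysis", "oxidative_tca", "reductive_branch",
              "bifurcated_tca", "ppp_shunt")) {
    t <- build_topology(p)
    for (r in t$reactions) {
      sub_c <- sum(metabolite_carbons(r$substrates))
      prod_c <- sum(metabolite_carbons(r$products))
      co2_in <- sum(vapply(r$atom_map, function(m) sum(m[, 1] == 0L), 0))
      losses <- if (is.null(r$losses)) 0L else nrow(r$losses)
      expect_equal(as.numeric(sub_c + co2_in), as.numeric(prod_c + losses),
                   info = paste(p, r$name))
    }
  }
})

test_that("the non-oxidative PPP block consumes 15 carbons and produces 15", {
  tk <- get_reaction(build_topology("ppp_shunt"), "TKTA")
  expect_identical(unname(sum(metabolite_carbons(tk$substrates))), 15L)
  expect_identical(unname(sum(metabolite_carbons(tk$products))), 15L)
  expect_identical(sum(vapply(tk$atom_map, nrow, 0L)), 15L)
})

test_that("validate_topology reports injected defects", {
  t <- build_topology("oxidative_tca")
  # delete one atom-map source entry -> carbon-conservation violation
  broken <- t
  broken$reactions$CS$atom_map[[1L]] <-
    broken$reactions$CS$atom_map[[1L]][-1L, ]
  v <- validate_topology(broken)
  expect_true(any(v$check %in% c("carbon_conservation", "atom_map_cover") &
                    v$reaction == "CS"))
  # duplicated pool name -> uniqueness violation
  dup <- t
  dup$pools <- c(dup$pools, dup$pools[1L])
  v2 <- validate_topology(dup)
  expect_true(any(v2$check == "unique_pools"))
})

test_that("contradictory preset options are rejected", {
  expect_error(build_topology("nonsense"))
  expect_error(build_topology("reductive_branch", include_sdh = TRUE),
               "include_sdh")
  expect_error(build_topology("bifurcated_tca", include_sdh = TRUE),
               "succinate dehydrogenase")
  expect_error(build_topology("glycolysis", include_fumarate_reductase = TRUE),
               "reductive")
  expect_error(build_topology("oxidative_tca", recycle_fraction = 1.5),
               "recycle_fraction")
})

test_that("packaged preset JSON files reproduce the constructors", {
  for (p in c("glycolysis", "oxidative_tca", "reductive_branch",
              "bifurcated_tca", "ppp_shunt")) {
    path <- system.file("extdata", "topologies", paste0(p, ".json"),
                        package = "tracefate")
    expect_true(nzchar(path), info = p)
    expect_equal(unclass(read_topology(path)),
                 unclass(build_topology(p)), info = p)
  }
})

test_that("topology JSON round-trips through a temp file", {
  t <- build_topology("bifurcated_tca", recycle_fraction = 0.25)
  f <- tempfile(fileext = ".json")
  write_topology(t, f)
  t2 <- read_topology(f)
  expect_equal(unclass(t2), unclass(t))
  # and simulates identically
  expect_equal(as.data.frame(simulate_labeling(t2, cfg = sim_config(2))),
               as.data.frame(simulate_labeling(t, cfg = sim_config(2))))
})
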