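tca <- build_topology("oxidative_tca")
gly <- build_topology("glycolysis")

test_that("condensation matches the paper's first-cycle expectation and the
           enumeration oracle", {
  cs <- get_reaction(tca, "CS")
  # M+2 acetyl + M+0 oxaloacetate -> citrate with all mass at popcount 2
  cit <- condense(unlabeled_dist("OAA"), fully_labeled_dist("ACA"), cs)
  expect_valid_dist(cit)
  expect_equal(collapse_to_mid(cit)$fractions[3L], 1)
  # no label in, none out
  cit0 <- condense(unlabeled_dist("OAA"), unlabeled_dist("ACA"), cs)
  expect_equal(cit0$w[1L], 1)
  # random substrates: equals exhaustive enumeration over all pattern pairs
  set.seed(11)
  for (i in 1:5) {
    a <- random_dist("OAA"); b <- random_dist("ACA")
    expect_equal(condense(a, b, cs)$w, oracle_condense(a, b, cs),
                 tolerance = 1e-12)
  }
  expect_error(condense(unlabeled_dist("FUM"), unlabeled_dist("ACA"), cs),
               "requires")
})

test_that("decarboxylation transform tracks product mass and CO2 label", {
  pdc <- get_reaction(gly, "PDC")
  full <- transform_dist(fully_labeled_dist("PYR"), pdc)
  expect_equal(collapse_to_mid(full$product)$fractions, c(0, 0, 1))
  expect_equal(full$co2_label_fraction, 1.0)
  none <- transform_dist(unlabeled_dist("PYR"), pdc)
  expect_equal(none$product$w[1L], 1)
  expect_equal(none$co2_label_fraction, 0.0)
  # labeled only at C1 (the lost carboxyl): product unlabeled, CO2 labeled
  c1 <- isotopomer_dist("PYR", c(0, 1, rep(0, 6)))
  out <- transform_dist(c1, pdc)
  expect_equal(out$product$w[1L], 1)
  expect_equal(out$co2_label_fraction, 1.0)
})

test_that("symmetrization averages mirror patterns, preserves MIDs, and is
           idempotent", {
  d <- isotopomer_dist("FUM", c(rep(0, 12), 1, rep(0, 3)))  # pattern 1100
  s <- symmetrize(d)
  expect_equal(s$w[13L], 0.5)  # 1100
  expect_equal(s$w[4L], 0.5)   # 0011
  set.seed(21)
  for (i in 1:5) {
    d <- random_dist(sample(c("FUM", "SUC"), 1))
    s <- symmetrize(d)
    expect_equal(collapse_to_mid(s)$fractions, collapse_to_mid(d)$fractions,
                 tolerance = 1e-12)
    expect_equal(symmetrize(s)$w, s$w, tolerance = 1e-12)
  }
  expect_error(symmetrize(random_dist("MAL")), "not a symmetric")
})

test_that("distributions stay normalized through every preset simulation", {
  set.seed(31)
  for (p in c("glycolysis", "oxidative_tca", "reductive_branch",
              "bifurcated_tca", "ppp_shunt")) {
    t <- build_topology(p)
    st <- pool_state(t, labeled = t$entry)
    cfg <- sim_config(n_turns = 3, mixing_fraction = 0.7)
    for (i in 1:3) {
      st <- step_turn(t, st, cfg)
      for (d in st$dists) expect_valid_dist(d)
    }
  }
})

test_that("one oxidative turn moves the acetyl label to M+2 fumarate and
           never beyond (stereospecificity)", {
  st <- pool_state(tca, labeled = c("PYR", "ACA"))
  st1 <- step_turn(tca, st, sim_config(mixing_fraction = 1))
  fum <- collapse_to_mid(st1$dists$FUM)$fractions
  expect_equal(fum[3L], 1)           # all labeled mass at M+2
  expect_equal(sum(fum[4:5]), 0)     # no popcount > 2 on the first turn
})

test_that("a zero-label state is a fixed point of label space", {
  st <- pool_state(tca)  # everything unlabeled, external CO2 unlabeled
  st1 <- step_turn(tca, st, sim_config())
  for (m in names(st$dists)) {
    expect_equal(st1$dists[[m]]$w, st$dists[[m]]$w, tolerance = 1e-12)
  }
})

test_that("repeated oxidative turns accumulate M+4 fumarate, absent after
           turn 1", {
  tc <- simulate_labeling(tca, pool_state(tca, labeled = c("PYR", "ACA")),
                          sim_config(n_turns = 6))
  fum <- as.data.frame(tc)[tc$metabolite == "FUM", ]
  expect_equal(fum$m4[fum$turn == 1], 0)
  expect_gt(fum$m4[fum$turn == 6], 0.5)
})

test_that("reductive branch from labeled pyruvate yields M+3 fumarate with
           unlabeled CO2 and M+4 oxaloacetate with a labeled CO2 pool", {
  red <- build_topology("reductive_branch", recycle_fraction = 0)
  tc <- simulate_labeling(red, pool_state(red, labeled = "PYR"),
                          sim_config(n_turns = 1))
  fum <- as.data.frame(tc)[tc$metabolite == "FUM" & tc$turn == 1, ]
  expect_equal(fum$m3, 1)
  # recycling: charge the CO2 pool by decarboxylating labeled pyruvate first
  bif <- build_topology("bifurcated_tca", recycle_fraction = 1)
  tcb <- simulate_labeling(bif, pool_state(bif, labeled = "PYR"),
                           sim_config(n_turns = 2))
  oaa <- as.data.frame(tcb)[tcb$metabolite == "OAA" & tcb$turn == 2, ]
  expect_gt(oaa$m4, 0.5)
})

test_that("per-reaction label balance holds across presets and inits", {
  set.seed(41)
  for (p in c("oxidative_tca", "bifurcated_tca", "ppp_shunt")) {
    t <- build_topology(p)
    for (rxn in t$reactions) {
      dists <- lapply(rxn$substrates, random_dist)
      out <- tracefate:::.react(dists, rxn, co2_q = stats::runif(1))
      expect_equal(out$audit[["label_in"]], out$audit[["label_out"]],
                   tolerance = 1e-9, info = paste(p, rxn$name))
    }
  }
})

test_that("a closed recycling cycle reaches a label-conserving fixed point", {
  # full recycling, no discarded losses: at the fixed point every pool's
  # label content is stationary and the CO2 ledger balances each turn
  # (labeled CO2 released == labeled CO2 re-fixed)
  t <- closed_cycle_topology(recycle_fraction = 1)
  s <- pool_state(t, labeled = "PYR")
  prev <- s
  for (turn in 1:25) {
    prev <- s
    s <- step_turn(t, s, sim_config(mixing_fraction = 1))
  }
  expect_equal(total_labeled_carbon(s), total_labeled_carbon(prev),
               tolerance = 1e-9)
  d_released <- s$co2[["released_labeled"]] - prev$co2[["released_labeled"]]
  d_fixed <- s$co2[["fixed_labeled"]] - prev$co2[["fixed_labeled"]]
  expect_equal(d_released, d_fixed, tolerance = 1e-9)
  # fixed point: every pool fully labeled (3 + 2 + 3 labeled carbons)
  expect_equal(total_labeled_carbon(s), 8, tolerance = 1e-6)
})

test_that("simulate_labeling is deterministic and records all turns", {
  tc1 <- simulate_labeling(tca, cfg = sim_config(n_turns = 3))
  tc2 <- simulate_labeling(tca, cfg = sim_config(n_turns = 3))
  expect_identical(as.data.frame(tc1), as.data.frame(tc2))
  expect_setequal(unique(tc1$turn), 0:3)
  expect_setequal(unique(tc1$metabolite), tca$pools)
})

test_that("fixed-point MIDs under m=1 agree with the Monte-Carlo oracle", {
  for (p in c("oxidative_tca", "reductive_branch")) {
    t <- build_topology(p)
    cfg_mc <- sim_config(n_turns = 2, seed = 101, n_molecules = 1e5)
    mc <- monte_carlo_labeling(t, cfg = cfg_mc)
    det <- as.data.frame(simulate_labeling(t, cfg = sim_config(n_turns = 2)))
    det <- det[det$turn == 2, ]
    for (i in seq_len(nrow(mc))) {
      dv <- det[det$metabolite == mc$metabolite[i],
                paste0("m", mc$k[i])]
      tol <- max(4 * mc$se[i], 1e-9)
      expect_lt(abs(mc$fraction[i] - dv), tol + 1e-12)
    }
  }
})

test_that("Monte-Carlo runs are reproducible per seed and keep unlabeled
           inputs unlabeled", {
  t <- build_topology("reductive_branch")
  cfg <- sim_config(n_turns = 1, seed = 5, n_molecules = 1000)
  a <- monte_carlo_labeling(t, cfg = cfg)
  b <- monte_carlo_labeling(t, cfg = cfg)
  expect_identical(a, b)
  init <- pool_state(t)  # no label anywhere
  mc <- monte_carlo_labeling(t, init, cfg)
  expect_equal(mc$fraction[mc$k == 0], rep(1, length(unique(mc$metabolite))))
})
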