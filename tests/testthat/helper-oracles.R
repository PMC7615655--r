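# Independent brute-force oracles used to check the vectorized propagation
# engine, plus small fixture builders. The oracles enumerate molecules /
# pattern pairs explicitly and share no code with the implementation.

# random valid isotopomer distribution
random_dist <- function(metabolite) {
  n <- unname(metabolite_carbons(metabolite))
  w <- stats::runif(2^n)
  isotopomer_dist(metabolite, w / sum(w))
}

# popcount of a single pattern code, by string conversion (independent of
# the package's bit arithmetic)
oracle_popcount <- function(code) {
  sum(as.integer(intToBits(code)) == 1L)
}

# brute-force condensation: loop over all 2^(na+nb) substrate pattern pairs,
# build the product pattern carbon by carbon from the atom map
oracle_condense <- function(a, b, rxn) {
  map <- rxn$atom_map[[1L]]
  nc <- nrow(map)
  out <- numeric(2^nc)
  for (pa in 0:(2^a$n - 1L)) {
    for (pb in 0:(2^b$n - 1L)) {
      bits_by_slot <- list(as.integer(intToBits(pa))[seq_len(a$n)],
                           as.integer(intToBits(pb))[seq_len(b$n)])
      code <- 0L
      for (i in seq_len(nc)) {
        bit <- bits_by_slot[[map[i, "slot"]]][map[i, "carbon"]]
        code <- code + bit * 2L^(i - 1L)
      }
      out[code + 1L] <- out[code + 1L] + a$w[pa + 1L] * b$w[pb + 1L]
    }
  }
  out
}

# brute-force MID: bin pattern weights by their popcount
oracle_mid <- function(d) {
  f <- numeric(d$n + 1L)
  for (p in seq_along(d$w)) {
    k <- oracle_popcount(p - 1L)
    f[k + 1L] <- f[k + 1L] + d$w[p]
  }
  f
}

# expected labeled carbons held in the metabolite pools of a state
total_labeled_carbon <- function(state) {
  sum(vapply(names(state$dists), function(m) {
    d <- state$dists[[m]]
    pc <- vapply(seq_along(d$w) - 1L, oracle_popcount, numeric(1))
    state$sizes[[m]] * sum(d$w * pc)
  }, numeric(1)))
}

# a closed three-reaction cycle (every pool produced and consumed once,
# equal sizes) used for the label-conservation property: A3 -> B2 + CO2,
# B2 + CO2_IN -> C3, C3 -> A3. PYR/ACA/GAP stand in for A/B/C.
closed_cycle_topology <- function(recycle_fraction = 1) {
  topology("closed_cycle", list(
    reaction("DC", "PYR", "ACA",
             atom_map = list(cbind(slot = c(1L, 1L), carbon = c(2L, 3L))),
             losses = cbind(1L, 1L), loss_to = "co2"),
    reaction("CX", "ACA", "GAP",
             atom_map = list(cbind(slot = c(1L, 1L, 0L),
                                   carbon = c(1L, 2L, 1L)))),
    reaction("BK", "GAP", "PYR", atom_map = list(cbind(slot = rep(1L, 3L),
                                                       carbon = 1:3)))
  ), recycle_fraction = recycle_fraction, entry = "PYR")
}

expect_valid_dist <- function(d) {
  expect_s3_class(d, "tf_isotopomer")
  expect_true(all(d$w >= 0))
  expect_equal(sum(d$w), 1, tolerance = 1e-9)
}
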