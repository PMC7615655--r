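mk_mix <- function() {
  data.frame(metabolite = c("SI", "FUM", "MAL"),
             nmol = c(1, 2, 1),
             integral = c(1e6, 4e6, 0.5e6))
}

test_that("response factors follow the internal-standard formula", {
  rf <- compute_mrrf(mk_mix())
  # (SI_nmol / met_nmol) * (met_int / SI_int)
  expect_equal(rf$mrrf[rf$metabolite == "FUM"], (1 / 2) * (4e6 / 1e6))
  expect_equal(rf$mrrf[rf$metabolite == "MAL"], 0.5)
  # a metabolite identical to the standard in amount and integral has MRRF 1
  self <- data.frame(metabolite = c("SI", "FUM"), nmol = c(1, 1),
                     integral = c(1e6, 1e6))
  expect_equal(compute_mrrf(self)$mrrf, 1)
  # linearity: doubling the mix integral doubles MRRF; doubling the mix
  # amount halves it
  m2 <- mk_mix(); m2$integral[2] <- m2$integral[2] * 2
  expect_equal(compute_mrrf(m2)$mrrf[1], 2 * 2)
  m3 <- mk_mix(); m3$nmol[2] <- m3$nmol[2] * 2
  expect_equal(compute_mrrf(m3)$mrrf[1], 1)
  bad <- mk_mix(); bad$integral[2] <- 0
  expect_error(compute_mrrf(bad), "positive")
  expect_error(compute_mrrf(mk_mix()[2:3, ]), "SI row")
})

test_that("quantification round-trips the standard mix exactly", {
  mix <- mk_mix()
  rf <- compute_mrrf(mix)
  # feed the mix itself through the sample branch
  samples <- data.frame(sample_id = "mix", metabolite = mix$metabolite,
                        integral = mix$integral)
  q <- quantify_samples(samples, rf, si_nmol = 1)
  expect_equal(q$nmol, mix$nmol[mix$metabolite != "SI"], tolerance = 1e-12)
  expect_true(all(q$flag == "ok"))
})

test_that("sample quantification follows the formula and flags unknowns", {
  rf <- data.frame(metabolite = "FUM", mrrf = 2)
  class(rf) <- c("tf_response_factors", "data.frame")
  s <- data.frame(sample_id = rep("a", 3),
                  metabolite = c("SI", "FUM", "CIT"),
                  integral = c(1, 4, 3))
  expect_warning(q <- quantify_samples(s, rf, si_nmol = 1), "CIT")
  expect_equal(q$nmol[q$metabolite == "FUM"], (4 / 1) * 1 / 2)
  expect_equal(q$nmol[q$metabolite == "CIT"], 3)
  expect_identical(q$flag[q$metabolite == "CIT"], "unquantified")
  # linear in the sample integral, inverse in the SI integral
  s2 <- s[1:2, ]; s2$integral[2] <- 8
  expect_equal(quantify_samples(s2, rf)$nmol, 4)
  s3 <- s[1:2, ]; s3$integral[1] <- 2
  expect_equal(quantify_samples(s3, rf)$nmol, 1)
  expect_error(quantify_samples(s[2, , drop = FALSE], rf), "internal-standard")
})

test_that("normalization helpers follow their formulas", {
  expect_equal(secreted_normalization(0, 6), 0)
  expect_equal(secreted_normalization(3, 6), 0.5)
  expect_equal(secreted_normalization(3, 6), secreted_normalization(30, 60))
  expect_true(is.na(secreted_normalization(3, 0)))
  expect_equal(glucose_uptake_rate(10, 0.5, 0.3), 6.0)
  expect_equal(glucose_uptake_rate(0, 0.5, 0.3), 0)
  expect_equal(glucose_uptake_rate(10, 0.5, 0.6),
               2 * glucose_uptake_rate(10, 0.5, 0.3))
  expect_error(glucose_uptake_rate(10, 0, 0.3), "delta_od")
  expect_equal(biomass_yield(1, 1), 1)
  expect_equal(biomass_yield(0.5, 2), 0.25)
  expect_equal(biomass_yield(500, 2000), biomass_yield(0.5, 2))
  expect_error(biomass_yield(0.5, 0), "delta_glucose")
})

test_that("recovery error from synthetic tables scales with the noise CV", {
  med_err <- vapply(c(0, 0.05, 0.2), function(cv) {
    spec <- generator_spec(noise_cv = cv, seed = 99)
    g <- gen_integral_table(spec, n_samples = 6)
    q <- quantify_samples(g$integrals, compute_mrrf(g$mix),
                          si_nmol = spec$si_nmol)
    rel <- abs(q$nmol - g$truth[q$metabolite]) / g$truth[q$metabolite]
    stats::median(rel)
  }, numeric(1))
  expect_equal(med_err[1], 0, tolerance = 1e-12)
  expect_lt(med_err[2], 0.10)
  expect_gt(med_err[3], med_err[2])
})
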