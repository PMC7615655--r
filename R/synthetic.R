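# Synthetic-data generators with known ground truth: GC-MS integral tables
# with an internal standard, label time courses under a chosen topology, and
# growth/glucose series. These emulate the statistical structure the
# analysis assumes (multiplicative log-normal intensity noise, 1 nmol
# scyllo-inositol internal standard, replicate layouts of six for abundance
# and four for tracing) so every pipeline stage can be tested end to end.

.DEFAULT_NMOL <- c(
  G6P = 0.8, F6P = 0.4, DHAP = 0.5, `3PGA` = 0.6, `2PGA` = 0.15, PEP = 0.3,
  PYR = 1.2, CIT = 0.9, AKG = 0.5, SUC = 0.7, FUM = 0.4, MAL = 1.0,
  OAA = 0.1, ASP = 1.5, G3P = 0.6, `6PGA` = 0.2, Ru5P = 0.2, R5P = 0.15,
  SH7P = 0.1, GLU = 5.0
)

.DEFAULT_MRRF <- c(
  G6P = 0.9, F6P = 0.85, DHAP = 1.4, `3PGA` = 1.1, `2PGA` = 1.05, PEP = 0.7,
  PYR = 2.1, CIT = 0.6, AKG = 0.8, SUC = 1.3, FUM = 1.2, MAL = 1.0,
  OAA = 0.5, ASP = 0.95, G3P = 1.15, `6PGA` = 0.45, Ru5P = 0.75, R5P = 0.8,
  SH7P = 0.35, GLU = 1.6
)

# multiplicative log-normal noise with unit mean and coefficient of
# variation cv
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Specify a synthetic-data generator
#'
#' @param nmol named numeric vector of true per-metabolite abundances
#'   (nmol); defaults to a realistic central-carbon panel.
#' @param mrrf named numeric vector of true molar relative response
#'   factors; defaults cover the same panel.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise (default 0.05, typical GC-MS technical variability).
#' @param si_nmol internal standard added per sample (default 1 nmol).
#' @param si_integral noise-free integral of the internal standard.
#' @param mix_nmol amount of each metabolite in the standard mix (scalar or
#'   named vector; default 1 nmol).
#' @param preset topology preset for label time courses.
#' @param cfg [sim_config()] for label time courses.
#' @param convolve_na forward-convolve generated MIDs with natural 13C
#'   abundance (default `FALSE`: simulator output is tracer-pure).
#' @param p13 natural 13C probability used when `convolve_na` is `TRUE`.
#' @param seed integer seed; with a seed set, generation is fully
#'   deterministic.
#' @return a `"tf_generator_spec"` list.
#' @export
generator_spec <- function(nmol = .DEFAULT_NMOL, mrrf = .DEFAULT_MRRF,
                           noise_cv = 0.05, si_nmol = 1, si_integral = 1e6,
                           mix_nmol = 1, preset = "bifurcated_tca",
                           cfg = sim_config(), convolve_na = FALSE,
                           p13 = 0.0107, seed = NULL) {
  stopifnot(noise_cv >= 0, si_nmol > 0, si_integral > 0,
            all(nmol > 0), all(mrrf > 0))
  if (is.null(names(mix_nmol))) {
    mix_nmol <- stats::setNames(rep(mix_nmol, length.out = length(nmol)),
                                names(nmol))
  }
  structure(list(nmol = nmol, mrrf = mrrf, noise_cv = noise_cv,
                 si_nmol = si_nmol, si_integral = si_integral,
                 mix_nmol = mix_nmol, preset = preset, cfg = cfg,
                 convolve_na = convolve_na, p13 = p13, seed = seed),
            class = "tf_generator_spec")
}

#' Generate a synthetic GC-MS integral table
#'
#' Sample integrals follow
#' `integral = MRRF * nmol / SI_nmol * SI_integral * noise`; the internal
#' standard row receives its own multiplicative noise. The standard mix is
#' generated noise-free from the same response factors, so the
#' quantification round trip is exact at zero noise.
#'
#' @param spec a [generator_spec()].
#' @param n_samples number of samples (default 6: two technical replicates
#'   over three biological repeats, the usual abundance layout).
#' @return list with `integrals` (sample table), `mix` (standard mix) and
#'   `truth` (named vector of true nmol).
#' @export
gen_integral_table <- function(spec, n_samples = 6L) {
  stopifnot(inherits(spec, "tf_generator_spec"), n_samples >= 1L)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mets <- names(spec$nmol)
  mix <- data.frame(
    metabolite = c("SI", mets),
    nmol = c(spec$si_nmol, unname(spec$mix_nmol[mets])),
    integral = c(spec$si_integral,
                 unname(spec$mrrf[mets] * spec$mix_nmol[mets] /
                          spec$si_nmol * spec$si_integral)),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n_samples), function(i) {
    noise <- .lnoise(length(mets) + 1L, spec$noise_cv)
    data.frame(
      sample_id = sprintf("S%02d", i),
      metabolite = c("SI", mets),
      integral = c(spec$si_integral * noise[1L],
                   unname(spec$mrrf[mets] * spec$nmol[mets] /
                            spec$si_nmol * spec$si_integral *
                            noise[-1L])),
      stringsAsFactors = FALSE)
  })
  list(integrals = do.call(rbind, rows), mix = mix, truth = spec$nmol)
}

#' Generate a synthetic label time course
#'
#' Runs [simulate_labeling()] under the spec's topology preset, optionally
#' forward-convolves each MID with natural 13C abundance, applies
#' multiplicative log-normal noise per MID component, and renormalizes each
#' MID to sum 1.
#'
#' @param spec a [generator_spec()].
#' @return list with `timecourse` (noisy `"label_timecourse"` data frame)
#'   and `truth` (the noise-free simulation).
#' @export
gen_label_timecourse <- function(spec) {
  stopifnot(inherits(spec, "tf_generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  t <- build_topology(spec$preset)
  clean <- simulate_labeling(t, cfg = spec$cfg)
  noisy <- as.data.frame(clean)
  cols <- paste0("m", 0:7)
  for (i in seq_len(nrow(noisy))) {
    f <- as.numeric(noisy[i, cols])
    live <- !is.na(f)
    if (spec$convolve_na) {
      f[live] <- natural_abundance_convolve(
        mid(noisy$metabolite[i], f[live]), spec$p13)$fractions
    }
    f[live] <- f[live] * .lnoise(sum(live), spec$noise_cv)
    f[live] <- f[live] / sum(f[live])
    noisy[i, cols] <- as.list(f)
  }
  list(timecourse = structure(noisy,
                              class = c("label_timecourse", "data.frame"),
                              topology = t$name),
       truth = clean)
}

#' Generate a synthetic growth and glucose-consumption series
#'
#' Exponential OD595 growth with consistent glucose depletion: the percent
#' glucose consumed is constructed so that [glucose_uptake_rate()] applied
#' to the noise-free series recovers `uptake` exactly.
#'
#' @param rate growth rate (1/h, > 0).
#' @param uptake true glucose uptake rate to embed.
#' @param duration hours of growth (default 4).
#' @param n_points number of samples along the series (default 9).
#' @param od0 starting OD595 (default 0.1).
#' @param noise_cv multiplicative noise CV on OD and glucose (default 0).
#' @param seed integer seed.
#' @return data frame with columns `time_h`, `od`, `glucose_pct_consumed`.
#' @export
gen_growth_glucose <- function(rate, uptake, duration = 4, n_points = 9L,
                               od0 = 0.1, noise_cv = 0, seed = NULL) {
  stopifnot(rate > 0, duration > 0, n_points >= 2L)
  if (!is.null(seed)) set.seed(seed)
  time_h <- seq(0, duration, length.out = n_points)
  od <- od0 * exp(rate * time_h)
  pct <- uptake * (od - od0) / rate
  od <- od * .lnoise(n_points, noise_cv)
  pct <- pct * .lnoise(n_points, noise_cv)
  od[1L] <- od0
  pct[1L] <- 0
  data.frame(time_h = time_h, od = od, glucose_pct_consumed = pct)
}
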