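# Mass-isotopologue distributions: collapse from positional isotopomers,
# natural-abundance correction, fractional labeling, labeled-pool synthesis
# and the diagnostic abundance ratios.

#' Construct a mass-isotopologue distribution (MID)
#'
#' An MID is the vector of fractions of a metabolite pool carrying
#' 0, 1, ..., n heavy carbons (M+0..M+n) - the popcount marginal of the
#' positional isotopomer distribution.
#'
#' @param metabolite canonical metabolite name.
#' @param fractions numeric vector of length `n_carbons + 1`, non-negative,
#'   summing to 1 (renormalized if within tolerance).
#' @return an object of class `"tf_mid"` with fields `metabolite`,
#'   `fractions`.
#' @export
mid <- function(metabolite, fractions) {
  metabolite <- canonical_metabolite(metabolite)
  n <- unname(metabolite_carbons(metabolite))
  f <- as.numeric(fractions)
  if (length(f) != n + 1L) {
    stop(sprintf("%s needs %d MID components (M+0..M+%d), got %d",
                 metabolite, n + 1L, n, length(f)))
  }
  if (any(f < -.NORM_TOL)) stop("negative MID components")
  f[f < 0] <- 0
  s <- sum(f)
  if (abs(s - 1) > 1e-6) stop("MID must sum to 1 (got ", s, ")")
  structure(list(metabolite = metabolite, fractions = f / s),
            class = "tf_mid")
}

#' @export
print.tf_mid <- function(x, ...) {
  cat("<MID>", x$metabolite, "\n")
  print(round(stats::setNames(x$fractions,
                              paste0("M+", seq_along(x$fractions) - 1L)), 4))
  invisible(x)
}

#' Collapse a positional isotopomer distribution to its MID
#'
#' M+k is the total weight of labeling patterns with exactly k labeled
#' carbons; the collapse is linear and mass-preserving.
#'
#' @param d a `"tf_isotopomer"`.
#' @return a `"tf_mid"`.
#' @export
collapse_to_mid <- function(d) {
  stopifnot(inherits(d, "tf_isotopomer"))
  pc <- .popcount(seq_along(d$w) - 1L)
  f <- vapply(0:d$n, function(k) sum(d$w[pc == k]), numeric(1))
  mid(d$metabolite, f)
}

# lower-triangular binomial natural-abundance matrix: entry (i, j) is the
# probability that a molecule with j tracer labels is observed at mass i,
# i.e. that i - j of its n - j unlabeled backbone carbons are natural 13C
.na_matrix <- function(n, p13) {
  C <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    C[(j:n) + 1L, j + 1L] <- stats::dbinom(0:(n - j), n - j, p13)
  }
  C
}

#' Forward-convolve an MID with natural 13C abundance
#'
#' Converts a tracer-pure MID into the MID that would be observed when each
#' unlabeled backbone carbon independently carries natural-abundance 13C with
#' probability `p13`. The inverse operation is
#' [natural_abundance_correct()].
#'
#' @param m a `"tf_mid"`.
#' @param p13 natural 13C probability per carbon (default 0.0107).
#' @return the observed-scale `"tf_mid"`.
#' @export
natural_abundance_convolve <- function(m, p13 = 0.0107) {
  stopifnot(inherits(m, "tf_mid"), p13 >= 0, p13 <= 0.05)
  n <- length(m$fractions) - 1L
  mid(m$metabolite, as.vector(.na_matrix(n, p13) %*% m$fractions))
}

#' Correct an observed MID for natural 13C abundance
#'
#' Solves the lower-triangular system `C x = observed`, where `C` is the
#' binomial natural-abundance matrix over the tracked backbone carbons
#' (derivatization atoms are not modeled). The forward substitution clamps
#' each component at zero as it is computed, so noise-driven negative
#' components are suppressed without leaking oscillating mass into higher
#' isotopologues; the result is renormalized. On an MID that is an exact
#' forward convolution the clamp never engages and the inversion is exact.
#'
#' @param observed the observed `"tf_mid"`.
#' @param p13 natural 13C probability per carbon, in `[0, 0.05]`
#'   (default 0.0107).
#' @return the tracer-scale `"tf_mid"`.
#' @examples
#' m <- mid("FUM", c(0.5, 0, 0.3, 0.2, 0))
#' round(natural_abundance_correct(natural_abundance_convolve(m))$fractions, 9)
#' @export
natural_abundance_correct <- function(observed, p13 = 0.0107) {
  stopifnot(inherits(observed, "tf_mid"))
  if (!(p13 >= 0 && p13 <= 0.05)) stop("p13 must lie in [0, 0.05]")
  n <- length(observed$fractions) - 1L
  C <- .na_matrix(n, p13)
  if (abs(det(C)) < 1e-12) {
    stop("natural-abundance matrix is numerically singular (p13 = ", p13, ")")
  }
  obs <- observed$fractions
  x <- numeric(n + 1L)
  for (j in 0:n) {
    resid <- obs[j + 1L] -
      if (j > 0) sum(C[j + 1L, 1:j] * x[1:j]) else 0
    x[j + 1L] <- max(0, resid / C[j + 1L, j + 1L])
  }
  if (sum(x) <= 0) stop("correction annihilated the MID; input inconsistent")
  mid(observed$metabolite, x / sum(x))
}

#' Fractional labeling of a pool
#'
#' The fraction of the metabolite pool containing at least one tracer
#' carbon: `1 - M+0` (a molecule-level, not carbon-weighted, statement).
#'
#' @param m a `"tf_mid"`.
#' @return fraction in `[0, 1]`.
#' @export
fractional_labeling <- function(m) {
  stopifnot(inherits(m, "tf_mid"))
  1 - m$fractions[1L]
}

#' Labeled amount of a metabolite at a time point
#'
#' Multiplies the fractional labeling by the total pool size, giving the
#' nmol of 13C-labeled metabolite present at the chosen turn / time point.
#' Dividing by the elapsed time gives a synthesis rate when the caller picks
#' a point inside the initial linear-increase window (for glycerol-3-
#' phosphate time courses that is the earliest sampled point).
#'
#' @param tc a `"label_timecourse"` (or a data frame with columns
#'   `metabolite`, `turn`, `pool_nmol`, `m0`).
#' @param metabolite pool of interest.
#' @param t recorded turn / time point.
#' @return nmol of labeled metabolite.
#' @export
labeled_synthesis <- function(tc, metabolite, t) {
  metabolite <- canonical_metabolite(metabolite)
  row <- tc[tc$metabolite == metabolite & tc$turn == t, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no unique record for ", metabolite, " at turn ", t)
  }
  (1 - row$m0) * row$pool_nmol
}

#' Diagnostic abundance ratios for glycolysis and the pentose phosphate
#' pathway
#'
#' Computes the ratio panel used to localize glycolytic and PPP bottlenecks:
#' `G6P/F6P`, `G6P/6PGA`, the oxidative-to-non-oxidative PPP ratio
#' `(6PGA + Ru5P)/(R5P + SH7P)`, the 3PGA share of the summed glycolytic
#' intermediates (G6P, F6P, DHAP, 3PGA, 2PGA, PEP, pyruvate), `Ru5P/R5P` and
#' `R5P/SH7P`. All ratios are scale-invariant in the abundances.
#'
#' @param q either a named numeric vector of abundances (nmol), or a
#'   quantification data frame with columns `metabolite` and `nmol`
#'   (averaged across samples).
#' @return named numeric vector of ratios; a ratio whose inputs are missing
#'   or whose denominator is zero is `NA`.
#' @examples
#' pool_diagnostics(c(G6P = 2, F6P = 1, `6PGA` = 1))
#' @export
pool_diagnostics <- function(q) {
  if (is.data.frame(q)) {
    stopifnot(all(c("metabolite", "nmol") %in% names(q)))
    q <- tapply(q$nmol, canonical_metabolite(q$metabolite), mean)
    q <- stats::setNames(as.numeric(q), names(q))
  }
  names(q) <- canonical_metabolite(names(q))
  g <- function(m) if (m %in% names(q)) unname(q[[m]]) else NA_real_
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  glyc <- c("G6P", "F6P", "DHAP", "3PGA", "2PGA", "PEP", "PYR")
  glyc_sum <- if (all(glyc %in% names(q))) sum(q[glyc]) else NA_real_
  c("G6P/F6P"   = ratio(g("G6P"), g("F6P")),
    "G6P/6PGA"  = ratio(g("G6P"), g("6PGA")),
    "oxPPP/nonoxPPP" = ratio(sum(g("6PGA"), g("Ru5P")),
                             sum(g("R5P"), g("SH7P"))),
    "3PGA/glycolytic_sum" = ratio(g("3PGA"), glyc_sum),
    "Ru5P/R5P"  = ratio(g("Ru5P"), g("R5P")),
    "R5P/SH7P"  = ratio(g("R5P"), g("SH7P")))
}
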