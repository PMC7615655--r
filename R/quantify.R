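# Internal-standard GC-MS quantification via molar relative response
# factors (MRRF), plus the secreted-metabolite, glucose-uptake and
# biomass-yield normalizations.

#' Compute molar relative response factors from a standard mix
#'
#' For each metabolite in the standard mix,
#' `MRRF = (SI_nmol_mm / met_nmol_mm) * (met_int_mm / SI_int_mm)`,
#' where `SI` is the scyllo-inositol internal standard and `mm` the standard
#' metabolite mix run alongside the samples.
#'
#' @param mix data frame with columns `metabolite`, `nmol`, `integral`,
#'   containing one `SI` (scyllo-inositol) row and one row per metabolite.
#' @return data frame of class `"tf_response_factors"` with columns
#'   `metabolite`, `mrrf`.
#' @examples
#' mix <- data.frame(metabolite = c("SI", "FUM"), nmol = c(1, 2),
#'                   integral = c(1e6, 4e6))
#' compute_mrrf(mix)  # FUM MRRF = (1/2) * (4e6/1e6) = 2
#' @export
compute_mrrf <- function(mix) {
  stopifnot(is.data.frame(mix),
            all(c("metabolite", "nmol", "integral") %in% names(mix)))
  mix$metabolite <- canonical_metabolite(mix$metabolite)
  if (any(mix$nmol <= 0) || any(mix$integral <= 0)) {
    stop("standard-mix amounts and integrals must be positive")
  }
  si <- mix[mix$metabolite == "SI", , drop = FALSE]
  if (nrow(si) != 1L) stop("standard mix needs exactly one SI row")
  met <- mix[mix$metabolite != "SI", , drop = FALSE]
  out <- data.frame(metabolite = met$metabolite,
                    mrrf = (si$nmol / met$nmol) * (met$integral / si$integral),
                    stringsAsFactors = FALSE)
  class(out) <- c("tf_response_factors", "data.frame")
  out
}

#' Quantify sample abundances from GC-MS integrals
#'
#' Converts per-sample ion-fragment integrals to nmol using the internal
#' standard and the response factors:
#' `met_nmol_s = (met_int_s / SI_int_s) * SI_nmol / MRRF(met)`.
#' Metabolites without a response factor are reported relative to the
#' internal standard (`integral / SI_integral`) and flagged
#' `"unquantified"`, with a warning.
#'
#' @param integrals data frame with columns `sample_id`, `metabolite`,
#'   `integral`; each sample must contain exactly one `SI` row with a
#'   positive integral.
#' @param rf a [compute_mrrf()] result.
#' @param si_nmol amount of internal standard added per sample (default
#'   1 nmol).
#' @return data frame with columns `sample_id`, `metabolite`, `nmol`,
#'   `flag` (`"ok"` or `"unquantified"`).
#' @export
quantify_samples <- function(integrals, rf, si_nmol = 1) {
  stopifnot(is.data.frame(integrals),
            all(c("sample_id", "metabolite", "integral") %in% names(integrals)),
            si_nmol > 0)
  integrals$metabolite <- canonical_metabolite(integrals$metabolite)
  if (any(integrals$integral < 0)) stop("negative integrals")
  mrrf <- stats::setNames(rf$mrrf, rf$metabolite)
  out <- lapply(split(integrals, integrals$sample_id), function(s) {
    si <- s[s$metabolite == "SI", , drop = FALSE]
    if (nrow(si) != 1L || si$integral <= 0) {
      stop("sample ", s$sample_id[1L],
           " lacks a single positive internal-standard row")
    }
    met <- s[s$metabolite != "SI", , drop = FALSE]
    rel <- met$integral / si$integral
    known <- met$metabolite %in% names(mrrf)
    data.frame(sample_id = met$sample_id, metabolite = met$metabolite,
               nmol = ifelse(known, rel * si_nmol / mrrf[met$metabolite], rel),
               flag = ifelse(known, "ok", "unquantified"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (any(out$flag == "unquantified")) {
    warning("no response factor for: ",
            paste(unique(out$metabolite[out$flag == "unquantified"]),
                  collapse = ", "),
            "; reported relative to internal standard")
  }
  out
}

#' Normalize a secreted-metabolite change to glucose consumed
#'
#' The change in a secreted metabolite relative to fresh medium divided by
#' the concomitant decrease in glucose.
#'
#' @param delta_met nmol change of the metabolite versus fresh medium.
#' @param delta_glucose nmol decrease in glucose (must be positive).
#' @return the ratio, or `NA` when `delta_glucose` is not positive.
#' @export
secreted_normalization <- function(delta_met, delta_glucose) {
  ifelse(delta_glucose > 0, delta_met / delta_glucose, NA_real_)
}

#' Glucose uptake rate
#'
#' Percent glucose consumed over an incubation window, normalized to the
#' change in culture density (OD595) over the same window, multiplied by the
#' strain's growth rate.
#'
#' @param pct_consumed percentage of glucose consumed.
#' @param delta_od OD595 change over the window (> 0).
#' @param growth_rate growth rate in 1/h (> 0).
#' @return the uptake rate `(pct_consumed / delta_od) * growth_rate`.
#' @export
glucose_uptake_rate <- function(pct_consumed, delta_od, growth_rate) {
  if (any(delta_od <= 0)) stop("delta_od must be positive")
  if (any(growth_rate <= 0)) stop("growth_rate must be positive")
  (pct_consumed / delta_od) * growth_rate
}

#' Biomass yield coefficient
#'
#' Dry weight of the culture divided by the glucose consumed over the growth
#' period (same mass units for both).
#'
#' @param dry_weight dry biomass (g).
#' @param delta_glucose glucose consumed (g, > 0).
#' @return the yield coefficient.
#' @export
biomass_yield <- function(dry_weight, delta_glucose) {
  if (any(delta_glucose <= 0)) stop("delta_glucose must be positive")
  dry_weight / delta_glucose
}
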