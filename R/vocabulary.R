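# Controlled vocabulary for metabolite identifiers. Backbone carbon counts
# cover every tracked species; the largest is sedoheptulose-7-phosphate (7C).

.MET_CARBONS <- c(
  GLC = 6L, G6P = 6L, F6P = 6L, FBP = 6L,
  DHAP = 3L, GAP = 3L, G3P = 3L, `3PGA` = 3L, `2PGA` = 3L, PEP = 3L,
  PYR = 3L, ACA = 2L, ACD = 2L, ETH = 2L,
  CIT = 6L, ICIT = 6L, AKG = 5L, SUC = 4L, FUM = 4L, MAL = 4L,
  OAA = 4L, ASP = 4L, GLU = 5L,
  `6PGA` = 6L, Ru5P = 5L, R5P = 5L, SH7P = 7L, E4P = 4L
)

# metabolites whose carbon skeleton has 2-fold rotational symmetry
.SYMMETRIC_METS <- c("SUC", "FUM")

.MET_SYNONYMS <- c(
  "glucose" = "GLC", "d-glucose" = "GLC",
  "glucose-6-phosphate" = "G6P", "fructose-6-phosphate" = "F6P",
  "fructose-1,6-bisphosphate" = "FBP", "f1,6bp" = "FBP",
  "dihydroxyacetone phosphate" = "DHAP",
  "glyceraldehyde-3-phosphate" = "GAP",
  "glycerol-3-phosphate" = "G3P",
  "3-phosphoglycerate" = "3PGA", "2-phosphoglycerate" = "2PGA",
  "phosphoenolpyruvate" = "PEP", "pyruvate" = "PYR",
  "acetyl-coa" = "ACA", "acetaldehyde" = "ACD", "ethanol" = "ETH",
  "citrate" = "CIT", "isocitrate" = "ICIT",
  "alpha-ketoglutarate" = "AKG", "a-ketoglutarate" = "AKG", "akg" = "AKG",
  "succinate" = "SUC", "fumarate" = "FUM", "malate" = "MAL",
  "oxaloacetate" = "OAA", "aspartate" = "ASP", "glutamate" = "GLU",
  "6-phosphogluconate" = "6PGA",
  "ribulose-5-phosphate" = "Ru5P", "ru5p" = "Ru5P",
  "ribose-5-phosphate" = "R5P",
  "sedoheptulose-7-phosphate" = "SH7P", "s7p" = "SH7P",
  "erythrose-4-phosphate" = "E4P",
  "scyllo-inositol" = "SI", "scyllo" = "SI"
)

#' Resolve metabolite names to canonical vocabulary identifiers
#'
#' Maps full names and common abbreviations (case-insensitively) onto the
#' package's controlled vocabulary (`G6P`, `F6P`, `DHAP`, `3PGA`, ...,
#' `SH7P`). Names already in the vocabulary, and unknown names, are returned
#' unchanged (unknown names may still be carried through quantification as
#' unquantified species).
#'
#' @param x character vector of metabolite names.
#' @return character vector of canonical identifiers.
#' @examples
#' canonical_metabolite(c("Fumarate", "ribulose-5-phosphate", "G6P"))
#' @export
canonical_metabolite <- function(x) {
  x <- as.character(x)
  out <- x
  # exact vocabulary hits (case-sensitive) stay as-is
  known <- out %in% c(names(.MET_CARBONS), "SI")
  lower <- tolower(out)
  hit <- !known & lower %in% names(.MET_SYNONYMS)
  out[hit] <- unname(.MET_SYNONYMS[lower[hit]])
  # case-insensitive vocabulary match (e.g. "fum" -> "FUM")
  rest <- !known & !hit
  if (any(rest)) {
    idx <- match(lower[rest], tolower(names(.MET_CARBONS)))
    out[rest][!is.na(idx)] <- names(.MET_CARBONS)[idx[!is.na(idx)]]
  }
  out
}

#' Backbone carbon count of a metabolite
#'
#' @param metabolite character vector of canonical metabolite names (see
#'   [canonical_metabolite()]).
#' @return integer vector of tracked backbone carbon counts.
#' @examples
#' metabolite_carbons(c("FUM", "SH7P"))
#' @export
metabolite_carbons <- function(metabolite) {
  metabolite <- canonical_metabolite(metabolite)
  n <- .MET_CARBONS[metabolite]
  if (anyNA(n)) {
    stop("unknown metabolite(s): ",
         paste(metabolite[is.na(n)], collapse = ", "))
  }
  stats::setNames(as.integer(n), metabolite)
}
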