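# File-format round-tripping: long/tidy CSV dialects for integral tables,
# standard mixes, label time courses and diagnostic profiles; JSON for
# topologies and run manifests. All readers are tolerant of extra columns
# (warning) and strict about missing ones (schema error naming them).

.SCHEMAS <- list(
  integrals     = c("sample_id", "metabolite", "integral"),
  mix           = c("metabolite", "nmol", "integral"),
  mid_timecourse = c("metabolite", "turn", "pool_nmol", paste0("m", 0:7)),
  profile       = c("diagnostic", "fraction"),
  quant         = c("sample_id", "metabolite", "nmol", "flag")
)

.read_schema <- function(path, schema) {
  stopifnot(schema %in% names(.SCHEMAS))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- .SCHEMAS[[schema]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("schema '", schema, "': ", basename(path),
         " is missing required column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring extra column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  }
  df[, need, drop = FALSE]
}

#' Read / write the package's CSV tables
#'
#' Long/tidy UTF-8 comma-separated files with a header row. Schemas:
#' `integrals` (`sample_id, metabolite, integral`), `mix`
#' (`metabolite, nmol, integral`), `mid_timecourse`
#' (`metabolite, turn, pool_nmol, m0..m7`; components beyond a metabolite's
#' carbon count are empty), `profile` (`diagnostic, fraction`). Writing then
#' reading any table is lossless on the canonical columns.
#'
#' @param path file path.
#' @return `read_integral_table()` and `read_standard_mix()` return data
#'   frames; `read_timecourse()` returns a `"label_timecourse"`;
#'   `read_diagnostic_profile()` returns the named fraction vector used by
#'   [infer_topologies()].
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_integral_table <- function(path) .read_schema(path, "integrals")

#' @rdname table_io
#' @export
read_standard_mix <- function(path) .read_schema(path, "mix")

#' @rdname table_io
#' @export
read_timecourse <- function(path) {
  df <- .read_schema(path, "mid_timecourse")
  for (col in paste0("m", 0:7)) df[[col]] <- as.numeric(df[[col]])
  structure(df, class = c("label_timecourse", "data.frame"),
            topology = NA_character_)
}

#' @rdname table_io
#' @param tc a `"label_timecourse"` data frame.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc)[, .SCHEMAS$mid_timecourse],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname table_io
#' @export
read_diagnostic_profile <- function(path) {
  df <- .read_schema(path, "profile")
  stats::setNames(as.numeric(df$fraction), df$diagnostic)
}

#' @rdname table_io
#' @param x a data frame (integral table, standard mix, quantification
#'   result) to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- topology JSON ----------------------------------------------------------

#' Serialize a topology to JSON / read one back
#'
#' The JSON schema is
#' `{name, entry, co2_policy: {recycle_fraction}, reactions: [{name,
#' substrates, products, atom_map, losses, loss_to, symmetric_products}]}`,
#' with each atom map given as a list (per product slot) of
#' `[slot, carbon]` rows (`slot` 0 = CO2 fixed from the pool). The shipped
#' preset files under `extdata/topologies/` use this schema.
#'
#' @param t a `"tf_topology"`.
#' @param path JSON file path.
#' @return `read_topology()` returns a validated `"tf_topology"`.
#' @examples
#' p <- system.file("extdata", "topologies", "oxidative_tca.json",
#'                  package = "tracefate")
#' read_topology(p)
#' @export
write_topology <- function(t, path) {
  stopifnot(inherits(t, "tf_topology"))
  obj <- list(
    name = t$name, entry = t$entry, pools = t$pools,
    co2_policy = t$co2_policy,
    reactions = lapply(unname(t$reactions), function(r) {
      list(name = r$name, substrates = r$substrates, products = r$products,
           atom_map = lapply(r$atom_map, function(m)
             lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))),
           losses = if (is.null(r$losses)) list() else
             lapply(seq_len(nrow(r$losses)), function(i)
               unname(r$losses[i, ])),
           loss_to = r$loss_to,
           symmetric_products = r$symmetric_products)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rxns <- lapply(obj$reactions, function(r) {
    reaction(
      name = r$name,
      substrates = unlist(r$substrates),
      products = unlist(r$products),
      atom_map = lapply(r$atom_map, function(m)
        do.call(rbind, lapply(m, unlist))),
      losses = if (length(r$losses))
        do.call(rbind, lapply(r$losses, unlist)) else NULL,
      loss_to = if (length(r$loss_to)) unlist(r$loss_to) else NULL,
      symmetric_products = if (length(r$symmetric_products))
        unlist(r$symmetric_products) else character())
  })
  t <- topology(obj$name, rxns, pools = unlist(obj$pools),
                recycle_fraction = obj$co2_policy$recycle_fraction,
                entry = obj$entry)
  v <- validate_topology(t)
  if (nrow(v)) {
    stop("topology in ", basename(path), " fails validation: ",
         paste(v$check, collapse = ", "))
  }
  t
}

#' Write a reproducibility manifest for an analysis run
#'
#' Records input paths, configuration, seed and package version as JSON so a
#' run's outputs can be reproduced from the manifest alone.
#'
#' @param path output JSON path.
#' @param inputs named list/vector of input file paths.
#' @param config named list of configuration values.
#' @param seed the run's seed (or `NULL`).
#' @return invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, inputs = list(), config = list(),
                               seed = NULL) {
  manifest <- list(
    package = "tracefate",
    version = as.character(utils::packageVersion("tracefate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, inputs = inputs, config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
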