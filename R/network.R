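# Carbon atom-transition networks: reactions with explicit atom maps and
# named topology presets for the pathway architectures under comparison.

#' Define a carbon-balanced reaction with an explicit atom map
#'
#' A reaction consumes one molecule from each substrate slot and produces one
#' molecule in each product slot. The atom map records, for every product
#' carbon, which substrate carbon it derives from (or that it is fixed from
#' the CO2 pool), and which substrate carbons are lost to CO2 or discarded.
#'
#' @param name reaction identifier (e.g. `"SDH"`).
#' @param substrates character vector of substrate slot metabolites (a
#'   metabolite may occupy several slots, as in the lumped non-oxidative
#'   pentose phosphate block).
#' @param products character vector of product slot metabolites.
#' @param atom_map list with one element per product slot; each element is an
#'   integer matrix with columns `slot` and `carbon` and one row per product
#'   carbon (row i gives the origin of product carbon i). `slot = 0` denotes
#'   a carbon fixed from the CO2 pool (`CO2_IN`).
#' @param losses integer matrix with columns `slot` and `carbon`, one row per
#'   substrate carbon not incorporated into any product; `NULL` when the
#'   reaction conserves all substrate carbons.
#' @param loss_to character vector, one per loss row, each `"co2"` (routed to
#'   the internal CO2 pool) or `"discard"`.
#' @param symmetric_products product metabolites whose carbon skeleton has
#'   2-fold rotational symmetry (succinate, fumarate); their isotopomer
#'   distributions are symmetrized on production.
#' @return an object of class `"tf_reaction"`.
#' @seealso [build_topology()], [validate_topology()]
#' @export
reaction <- function(name, substrates, products, atom_map,
                     losses = NULL, loss_to = NULL,
                     symmetric_products = character()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(substrates), length(substrates) >= 1L,
            is.character(products), length(products) >= 1L,
            is.list(atom_map), length(atom_map) == length(products))
  atom_map <- lapply(atom_map, function(m) {
    m <- matrix(as.integer(m), ncol = 2L,
                dimnames = list(NULL, c("slot", "carbon")))
    m
  })
  if (!is.null(losses)) {
    losses <- matrix(as.integer(losses), ncol = 2L,
                     dimnames = list(NULL, c("slot", "carbon")))
    if (is.null(loss_to)) loss_to <- rep("co2", nrow(losses))
    stopifnot(length(loss_to) == nrow(losses),
              all(loss_to %in% c("co2", "discard")))
  } else {
    loss_to <- character()
  }
  structure(
    list(name = name, substrates = substrates, products = products,
         atom_map = atom_map, losses = losses, loss_to = loss_to,
         symmetric_products = symmetric_products),
    class = "tf_reaction"
  )
}

# identity atom map: product carbon i <- (slot, i)
.imap <- function(slot, n) cbind(slot = rep(slot, n), carbon = seq_len(n))

#' Assemble a topology from reactions
#'
#' @param name topology identifier.
#' @param reactions list of [reaction()] objects, applied in order on each
#'   simulation turn.
#' @param pools character vector of metabolite pools; defaults to every
#'   metabolite referenced by the reactions.
#' @param recycle_fraction fraction `r` in `[0, 1]` of carboxylation carbon
#'   drawn from the internal released-CO2 pool; the remainder is unlabeled
#'   external CO2.
#' @param entry metabolite seeded as the fully labeled tracer entry point by
#'   [predict_diagnostics()]; defaults to the first substrate of the first
#'   reaction.
#' @return an object of class `"tf_topology"`.
#' @export
topology <- function(name, reactions, pools = NULL, recycle_fraction = 0,
                     entry = NULL) {
  stopifnot(is.list(reactions), length(reactions) >= 1L,
            all(vapply(reactions, inherits, TRUE, "tf_reaction")))
  if (!(is.numeric(recycle_fraction) && length(recycle_fraction) == 1L &&
        recycle_fraction >= 0 && recycle_fraction <= 1)) {
    stop("recycle_fraction must be a single number in [0, 1]")
  }
  mets <- unique(unlist(lapply(reactions, function(r)
    c(r$substrates, r$products))))
  if (is.null(pools)) pools <- mets
  if (is.null(entry)) entry <- reactions[[1L]]$substrates[1L]
  names(reactions) <- vapply(reactions, `[[`, "", "name")
  structure(
    list(name = name, reactions = reactions, pools = pools,
         co2_policy = list(recycle_fraction = recycle_fraction),
         entry = entry),
    class = "tf_topology"
  )
}

#' @export
print.tf_topology <- function(x, ...) {
  cat("<topology>", x$name, "\n")
  cat("  pools:", paste(x$pools, collapse = ", "), "\n")
  cat("  CO2 recycle fraction:", x$co2_policy$recycle_fraction, "\n")
  cat("  reactions (per-turn order):\n")
  for (r in x$reactions) {
    cat(sprintf("    %-6s %s -> %s%s\n", r$name,
                paste(r$substrates, collapse = " + "),
                paste(r$products, collapse = " + "),
                if (!is.null(r$losses) && any(r$loss_to == "co2"))
                  " + CO2" else ""))
  }
  invisible(x)
}

# ---- preset reaction sets ---------------------------------------------------

# Oxidative TCA atom maps use stereospecific (textbook) carbon transitions:
# both CO2 molecules released in the first oxidative turn derive from
# oxaloacetate-origin carbons, so acetyl carbons survive to succinate and a
# first turn seeded with labeled acetyl yields M+2 down to fumarate.
.rxn_PDH <- function(product = "ACA") {
  reaction("PDH", "PYR", product,
           atom_map = list(cbind(slot = c(1L, 1L), carbon = c(2L, 3L))),
           losses = cbind(1L, 1L), loss_to = "co2")
}

.rxn_oxidative <- function(include_sdh = TRUE) {
  rxns <- list(
    .rxn_PDH(),
    reaction("CS", c("OAA", "ACA"), "CIT",
             atom_map = list(rbind(.imap(1L, 4L),
                                   cbind(slot = c(2L, 2L), carbon = c(1L, 2L))))),
    reaction("ACO", "CIT", "ICIT", atom_map = list(.imap(1L, 6L))),
    # isocitrate dehydrogenase: CO2 from the oxaloacetate-derived C1
    reaction("IDH", "ICIT", "AKG",
             atom_map = list(cbind(slot = rep(1L, 5L),
                                   carbon = c(4L, 3L, 2L, 5L, 6L))),
             losses = cbind(1L, 1L), loss_to = "co2"),
    # aKG dehydrogenase + succinyl-CoA ligase, lumped; CO2 again OAA-derived
    reaction("AKGDH", "AKG", "SUC",
             atom_map = list(cbind(slot = rep(1L, 4L),
                                   carbon = c(2L, 3L, 4L, 5L))),
             losses = cbind(1L, 1L), loss_to = "co2",
             symmetric_products = "SUC")
  )
  if (include_sdh) {
    rxns <- c(rxns, list(
      reaction("SDH", "SUC", "FUM", atom_map = list(.imap(1L, 4L)),
               symmetric_products = "FUM"),
      reaction("FH", "FUM", "MAL", atom_map = list(.imap(1L, 4L))),
      reaction("MDH", "MAL", "OAA", atom_map = list(.imap(1L, 4L)))
    ))
  }
  rxns
}

# Reductive branch: pyruvate carboxylase maps pyruvate C1-C3 onto OAA C1-C3
# and fixes CO2 into the C4 carboxyl (standard flux-analysis convention; MID
# results do not depend on which terminal carboxyl is chosen).
.rxn_reductive <- function(include_fumarate_reductase = TRUE) {
  rxns <- list(
    reaction("PC", "PYR", "OAA",
             atom_map = list(rbind(.imap(1L, 3L),
                                   cbind(slot = 0L, carbon = 1L)))),
    reaction("MDHr", "OAA", "MAL", atom_map = list(.imap(1L, 4L))),
    reaction("FHr", "MAL", "FUM", atom_map = list(.imap(1L, 4L)),
             symmetric_products = "FUM")
  )
  if (include_fumarate_reductase) {
    rxns <- c(rxns, list(
      reaction("FRD", "FUM", "SUC", atom_map = list(.imap(1L, 4L)),
               symmetric_products = "SUC")
    ))
  }
  rxns
}

.rxn_glycolysis <- function() {
  list(
    reaction("HK", "GLC", "G6P", atom_map = list(.imap(1L, 6L))),
    reaction("PGI", "G6P", "F6P", atom_map = list(.imap(1L, 6L))),
    reaction("PFK", "F6P", "FBP", atom_map = list(.imap(1L, 6L))),
    reaction("ALD", "FBP", c("DHAP", "GAP"),
             atom_map = list(cbind(slot = rep(1L, 3L), carbon = 1:3),
                             cbind(slot = rep(1L, 3L), carbon = 4:6))),
    reaction("TPI", "DHAP", "GAP",
             atom_map = list(cbind(slot = rep(1L, 3L), carbon = c(3L, 2L, 1L)))),
    reaction("GAPDH", "GAP", "3PGA", atom_map = list(.imap(1L, 3L))),
    reaction("PGM", "3PGA", "2PGA", atom_map = list(.imap(1L, 3L))),
    reaction("ENO", "2PGA", "PEP", atom_map = list(.imap(1L, 3L))),
    reaction("PK", "PEP", "PYR", atom_map = list(.imap(1L, 3L))),
    # fermentative tail: pyruvate decarboxylase loses the C1 carboxyl to CO2
    reaction("PDC", "PYR", "ACD",
             atom_map = list(cbind(slot = c(1L, 1L), carbon = c(2L, 3L))),
             losses = cbind(1L, 1L), loss_to = "co2"),
    reaction("ADH", "ACD", "ETH", atom_map = list(.imap(1L, 2L)))
  )
}

# Non-oxidative PPP as one lumped carbon-balanced block implementing the
# canonical transketolase/transaldolase atom routing for the net conversion
# 3 x Ru5P (slots: Xu5P-role, R5P-role, Xu5P-role) -> 2 x F6P + 1 x GAP.
.rxn_ppp <- function() {
  list(
    reaction("G6PDH", "G6P", "6PGA", atom_map = list(.imap(1L, 6L))),
    reaction("6PGD", "6PGA", "Ru5P",
             atom_map = list(cbind(slot = rep(1L, 5L), carbon = 2:6)),
             losses = cbind(1L, 1L), loss_to = "co2"),
    reaction("TKTA", c("Ru5P", "Ru5P", "Ru5P"), c("F6P", "F6P", "GAP"),
             atom_map = list(
               # F6P #1 = Xu5P(1) C1-C2 + R5P(2) C1 + Xu5P(1) C3-C5 via TA
               cbind(slot   = c(1L, 1L, 2L, 1L, 1L, 1L),
                     carbon = c(1L, 2L, 1L, 3L, 4L, 5L)),
               # F6P #2 = Xu5P(3) C1-C2 + E4P (= R5P(2) C2-C5) via TK
               cbind(slot   = c(3L, 3L, 2L, 2L, 2L, 2L),
                     carbon = c(1L, 2L, 2L, 3L, 4L, 5L)),
               # GAP = Xu5P(3) C3-C5
               cbind(slot   = c(3L, 3L, 3L),
                     carbon = c(3L, 4L, 5L))))
  )
}

#' Build a named topology preset
#'
#' Presets encode the pathway architectures compared in fission-yeast carbon
#' metabolism: plain glycolysis with a fermentative tail; the oxidative TCA
#' cycle (citrate synthase through succinate dehydrogenase back to
#' oxaloacetate); the reductive TCA branch (pyruvate carboxylation down to
#' succinate via fumarate reductase); their union, the bifurcated TCA pathway
#' (no succinate dehydrogenase step) with optional endogenous bicarbonate
#' recycling; and the pentose phosphate shunt (oxidative decarboxylation plus
#' the lumped non-oxidative recombination 3 C5 -> 2 C6 + 1 C3).
#'
#' @param preset one of `"glycolysis"`, `"oxidative_tca"`,
#'   `"reductive_branch"`, `"bifurcated_tca"`, `"ppp_shunt"`.
#' @param recycle_fraction fraction of carboxylation carbon drawn from the
#'   internal released-CO2 pool (default 0 except `bifurcated_tca`, where the
#'   architecture's signature M+4 oxaloacetate requires recycling and the
#'   default is 0.5).
#' @param include_sdh keep the succinate dehydrogenase step (oxidative
#'   variants only). `FALSE` truncates the oxidative preset after
#'   succinyl-CoA ligase.
#' @param include_fumarate_reductase keep the fumarate -> succinate step in
#'   the reductive branch.
#' @return a validated `"tf_topology"`.
#' @examples
#' build_topology("oxidative_tca")
#' build_topology("bifurcated_tca", recycle_fraction = 1)
#' @export
build_topology <- function(preset = c("glycolysis", "oxidative_tca",
                                      "reductive_branch", "bifurcated_tca",
                                      "ppp_shunt"),
                           recycle_fraction = NULL,
                           include_sdh = TRUE,
                           include_fumarate_reductase = TRUE) {
  preset <- match.arg(preset)
  if (preset %in% c("glycolysis", "ppp_shunt", "reductive_branch") &&
      !missing(include_sdh)) {
    stop("include_sdh is only meaningful for oxidative/bifurcated presets")
  }
  if (preset %in% c("glycolysis", "ppp_shunt", "oxidative_tca") &&
      !missing(include_fumarate_reductase)) {
    stop("include_fumarate_reductase applies only to presets containing ",
         "the reductive branch")
  }
  if (preset == "bifurcated_tca" && !missing(include_sdh) && include_sdh) {
    stop("the bifurcated architecture has no succinate dehydrogenase step; ",
         "include_sdh = TRUE contradicts preset = 'bifurcated_tca'")
  }
  if (is.null(recycle_fraction)) {
    recycle_fraction <- if (preset == "bifurcated_tca") 0.5 else 0
  }
  t <- switch(preset,
    glycolysis = topology("glycolysis", .rxn_glycolysis(),
                          recycle_fraction = recycle_fraction, entry = "GLC"),
    oxidative_tca = topology("oxidative_tca",
                             .rxn_oxidative(include_sdh = include_sdh),
                             recycle_fraction = recycle_fraction,
                             entry = "PYR"),
    reductive_branch = topology(
      "reductive_branch",
      .rxn_reductive(include_fumarate_reductase = include_fumarate_reductase),
      recycle_fraction = recycle_fraction, entry = "PYR"),
    bifurcated_tca = topology(
      "bifurcated_tca",
      c(.rxn_oxidative(include_sdh = FALSE),
        .rxn_reductive(include_fumarate_reductase = include_fumarate_reductase)),
      recycle_fraction = recycle_fraction, entry = "PYR"),
    ppp_shunt = topology("ppp_shunt", .rxn_ppp(),
                         recycle_fraction = recycle_fraction, entry = "G6P")
  )
  v <- validate_topology(t)
  if (nrow(v) > 0L) stop("internal error: preset fails validation")
  t
}

#' Validate a topology
#'
#' Checks, for every reaction, that each product carbon has exactly one
#' source, that every substrate carbon appears exactly once across product
#' sources and losses (carbon conservation), and that slot/carbon indices are
#' in range; checks pool-name uniqueness; and checks that every product is
#' reachable from the declared entry metabolite together with pools that no
#' reaction produces (the topology's inputs).
#'
#' @param t a `"tf_topology"`.
#' @return a data frame of violations with columns `reaction` (`NA` for
#'   topology-level checks), `check` and `detail`; zero rows when valid.
#' @export
validate_topology <- function(t) {
  stopifnot(inherits(t, "tf_topology"))
  bad <- list()
  note <- function(reaction, check, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(
      reaction = reaction, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(t$pools)) {
    note(NA_character_, "unique_pools",
         paste("duplicated pool name:",
               paste(unique(t$pools[duplicated(t$pools)]), collapse = ", ")))
  }
  for (r in t$reactions) {
    miss <- setdiff(c(r$substrates, r$products), t$pools)
    if (length(miss)) {
      note(r$name, "pool_membership",
           paste("metabolite not in pool list:", paste(miss, collapse = ", ")))
    }
    ns <- tryCatch(metabolite_carbons(r$substrates),
                   error = function(e) NULL)
    np <- tryCatch(metabolite_carbons(r$products),
                   error = function(e) NULL)
    if (is.null(ns) || is.null(np)) {
      note(r$name, "known_metabolites", "unknown metabolite in reaction")
      next
    }
    used <- character()  # "slot.carbon" tags consumed so far
    ok <- TRUE
    co2_in <- 0L
    for (p in seq_along(r$products)) {
      m <- r$atom_map[[p]]
      if (nrow(m) != np[p]) {
        note(r$name, "atom_map_cover",
             sprintf("product %s has %d carbons but %d map rows",
                     r$products[p], np[p], nrow(m)))
        ok <- FALSE
        next
      }
      for (i in seq_len(nrow(m))) {
        if (m[i, "slot"] == 0L) { co2_in <- co2_in + 1L; next }
        if (m[i, "slot"] > length(r$substrates) ||
            m[i, "carbon"] > ns[m[i, "slot"]]) {
          note(r$name, "atom_map_range",
               sprintf("source (%d,%d) out of range", m[i, 1], m[i, 2]))
          ok <- FALSE
          next
        }
        used <- c(used, paste0(m[i, "slot"], ".", m[i, "carbon"]))
      }
    }
    if (!is.null(r$losses)) {
      for (i in seq_len(nrow(r$losses))) {
        if (r$losses[i, "slot"] > length(r$substrates) ||
            r$losses[i, "carbon"] > ns[r$losses[i, "slot"]]) {
          note(r$name, "loss_range",
               sprintf("loss (%d,%d) out of range",
                       r$losses[i, 1], r$losses[i, 2]))
          ok <- FALSE
          next
        }
        used <- c(used, paste0(r$losses[i, "slot"], ".", r$losses[i, "carbon"]))
      }
    }
    if (ok) {
      all_src <- unlist(lapply(seq_along(r$substrates), function(s)
        paste0(s, ".", seq_len(ns[s]))))
      if (anyDuplicated(used) || !setequal(used, all_src)) {
        note(r$name, "carbon_conservation",
             sprintf("substrate carbons used %d time(s) across %d positions; %d + %d CO2_IN expected",
                     length(used), length(all_src), length(all_src), co2_in))
      }
    }
  }
  # reachability: every produced metabolite must be derivable from the pools
  # (all pools are initialized at simulation start, so each declared pool is
  # an admissible input); this flags reactions stranded behind metabolites
  # missing from the pool list
  produced <- unique(unlist(lapply(t$reactions, `[[`, "products")))
  reach <- t$pools
  repeat {
    grew <- FALSE
    for (r in t$reactions) {
      if (all(r$substrates %in% reach) && !all(r$products %in% reach)) {
        reach <- union(reach, r$products)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  unreach <- setdiff(produced, reach)
  if (length(unreach)) {
    note(NA_character_, "reachability",
         paste("not reachable from inputs:", paste(unreach, collapse = ", ")))
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(reaction = character(), check = character(),
               detail = character(), stringsAsFactors = FALSE)
}

#' Retrieve a reaction from a topology by name
#'
#' @param t a `"tf_topology"`.
#' @param name reaction name, e.g. `"PDC"`.
#' @return the `"tf_reaction"`.
#' @export
get_reaction <- function(t, name) {
  stopifnot(inherits(t, "tf_topology"))
  r <- t$reactions[[name]]
  if (is.null(r)) stop("no reaction named '", name, "' in ", t$name)
  r
}
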