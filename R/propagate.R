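# Turn-based label propagation through a topology, with CO2-pool
# bookkeeping, plus a molecule-level Monte-Carlo implementation of the same
# semantics used as an independent cross-check.

#' Simulation configuration
#'
#' @param n_turns number of reaction-sequence turns to simulate; the turn
#'   index is the discrete counterpart of the tracing experiment's "cycle"
#'   (mapping turns onto minutes is left to the user as metadata).
#' @param mixing_fraction fraction `m` in `(0, 1]` of each product pool
#'   replaced by newly synthesized material each time its producing reaction
#'   fires; `m < 1` reproduces the pre-steady-state mixtures sampled in a
#'   label-switch time course.
#' @param seed integer seed (Monte-Carlo only).
#' @param n_molecules molecules per pool (Monte-Carlo only).
#' @return a `"tf_sim_config"` list.
#' @export
sim_config <- function(n_turns = 6L, mixing_fraction = 1,
                       seed = NULL, n_molecules = NULL) {
  stopifnot(n_turns >= 1L, mixing_fraction > 0, mixing_fraction <= 1)
  if (!is.null(n_molecules)) stopifnot(n_molecules >= 1)
  structure(list(n_turns = as.integer(n_turns),
                 mixing_fraction = mixing_fraction,
                 seed = seed, n_molecules = n_molecules),
            class = "tf_sim_config")
}

#' Initialize pool state for a topology
#'
#' Every pool receives an isotopomer distribution (unlabeled unless listed in
#' `labeled` or overridden in `dists`) and a pool size in nmol. The CO2 pool
#' starts empty (no released CO2, labeled fraction 0).
#'
#' @param t a `"tf_topology"`.
#' @param labeled metabolites initialized fully 13C-labeled (tracer
#'   entry points, e.g. `"PYR"` after a switch to uniformly labeled glucose).
#' @param sizes named numeric vector of pool sizes in nmol (default 1 for
#'   every pool); unnamed scalar recycles to all pools.
#' @param dists named list of `"tf_isotopomer"` overrides.
#' @return a `"tf_pool_state"` with fields `dists`, `sizes`, `co2`.
#' @export
pool_state <- function(t, labeled = character(), sizes = 1, dists = list()) {
  stopifnot(inherits(t, "tf_topology"))
  labeled <- canonical_metabolite(labeled)
  dd <- stats::setNames(lapply(t$pools, function(m) {
    if (m %in% labeled) fully_labeled_dist(m) else unlabeled_dist(m)
  }), t$pools)
  for (m in names(dists)) {
    stopifnot(inherits(dists[[m]], "tf_isotopomer"))
    dd[[canonical_metabolite(m)]] <- dists[[m]]
  }
  if (is.null(names(sizes))) {
    sizes <- stats::setNames(rep(as.numeric(sizes), length.out =
                                   length(t$pools)), t$pools)
  } else {
    full <- stats::setNames(rep(1, length(t$pools)), t$pools)
    full[canonical_metabolite(names(sizes))] <- as.numeric(sizes)
    sizes <- full
  }
  stopifnot(all(is.finite(sizes)), all(sizes >= 0))
  structure(list(dists = dd, sizes = sizes,
                 co2 = c(released_total = 0, released_labeled = 0,
                         fixed_total = 0, fixed_labeled = 0)),
            class = "tf_pool_state")
}

#' Labeled fraction of the internal released-CO2 pool
#'
#' The internal CO2 pool is the running mixture of all CO2 released by
#' decarboxylating reactions so far; its labeled fraction is what a
#' carboxylation drawing on endogenous bicarbonate samples from.
#'
#' @param state a `"tf_pool_state"`.
#' @return fraction in `[0, 1]` (0 while nothing has been released).
#' @export
co2_labeled_fraction <- function(state) {
  co2 <- state$co2
  if (co2[["released_total"]] <= 0) return(0)
  unname(co2[["released_labeled"]] / co2[["released_total"]])
}

#' Advance the pool state by one turn
#'
#' Applies the topology's reactions in order. Each firing reaction draws its
#' substrates from the current (within-turn, sequentially updated) pool
#' distributions and produces new material; a product pool holding old
#' material `old` that has received contributions `c1..cj` so far this turn
#' becomes `(1 - m) * old + m * mean(c1..cj)`, so several reactions feeding
#' one pool (e.g. both TCA branches producing succinate) blend with equal
#' weight rather than overwriting each other. CO2 released is added to the
#' internal pool (a running mixture); carboxylations draw labeled carbon
#' with probability `recycle_fraction * co2_labeled_fraction(state)`, the
#' remainder coming from the unlabeled external reservoir.
#'
#' @param t a `"tf_topology"`.
#' @param state a `"tf_pool_state"` covering `t`'s pools.
#' @param cfg a [sim_config()].
#' @return the updated `"tf_pool_state"`.
#' @export
step_turn <- function(t, state, cfg = sim_config()) {
  stopifnot(inherits(t, "tf_topology"), inherits(state, "tf_pool_state"))
  m <- cfg$mixing_fraction
  r_recycle <- t$co2_policy$recycle_fraction
  turn_start <- lapply(state$dists, `[[`, "w")
  contribs <- list()  # per-pool new-material contributions this turn
  for (rxn in t$reactions) {
    subs <- state$dists[rxn$substrates]
    if (any(vapply(subs, is.null, TRUE))) {
      stop("reaction ", rxn$name, " draws on an uninitialized pool")
    }
    q <- r_recycle * co2_labeled_fraction(state)
    out <- .react(subs, rxn, co2_q = q)
    # moles processed this firing: m times the (first) product pool size
    flux <- m * state$sizes[[rxn$products[1L]]]
    # aggregate product slots by metabolite (equal stoichiometric weight)
    for (met in unique(rxn$products)) {
      slots <- which(rxn$products == met)
      neww <- Reduce(`+`, lapply(out$products[slots], `[[`, "w")) /
        length(slots)
      contribs[[met]] <- c(contribs[[met]], list(neww))
      blended <- Reduce(`+`, contribs[[met]]) / length(contribs[[met]])
      mixed <- (1 - m) * turn_start[[met]] + m * blended
      state$dists[[met]]$w <- mixed / sum(mixed)
    }
    if (length(out$loss_frac)) {
      rel <- out$loss_to == "co2"
      if (any(rel)) {
        state$co2[["released_total"]] <- state$co2[["released_total"]] +
          flux * sum(rel)
        state$co2[["released_labeled"]] <- state$co2[["released_labeled"]] +
          flux * sum(out$loss_frac[rel])
      }
    }
    if (out$n_co2_in > 0L) {
      state$co2[["fixed_total"]] <- state$co2[["fixed_total"]] +
        flux * out$n_co2_in * r_recycle
      state$co2[["fixed_labeled"]] <- state$co2[["fixed_labeled"]] +
        flux * out$n_co2_in * q
    }
  }
  state
}

#' Simulate a label time course
#'
#' Runs [step_turn()] for `cfg$n_turns` turns and records, per turn and
#' metabolite, the pool size and the mass-isotopologue distribution
#' (M+0..M+7 columns; carbons beyond a metabolite's backbone are `NA`).
#' Deterministic given its inputs.
#'
#' @param t a `"tf_topology"`.
#' @param init a [pool_state()]; defaults to all pools unlabeled except the
#'   topology's tracer entry metabolite, fully labeled.
#' @param cfg a [sim_config()].
#' @return a `"label_timecourse"` data frame with columns `metabolite`,
#'   `turn`, `pool_nmol`, `m0`..`m7` (turn 0 is the initial state).
#' @examples
#' tc <- simulate_labeling(build_topology("oxidative_tca"),
#'                         cfg = sim_config(n_turns = 4))
#' subset(tc, metabolite == "FUM")
#' @export
simulate_labeling <- function(t, init = NULL, cfg = sim_config()) {
  stopifnot(inherits(t, "tf_topology"))
  if (is.null(init)) init <- pool_state(t, labeled = t$entry)
  state <- init
  rows <- list(.tc_rows(state, 0L))
  for (turn in seq_len(cfg$n_turns)) {
    state <- step_turn(t, state, cfg)
    rows[[turn + 1L]] <- .tc_rows(state, turn)
  }
  tc <- do.call(rbind, rows)
  rownames(tc) <- NULL
  structure(tc, class = c("label_timecourse", "data.frame"),
            topology = t$name, final_state = state)
}

.tc_rows <- function(state, turn) {
  mets <- names(state$dists)
  mid <- matrix(NA_real_, nrow = length(mets), ncol = 8L,
                dimnames = list(NULL, paste0("m", 0:7)))
  for (i in seq_along(mets)) {
    f <- collapse_to_mid(state$dists[[mets[i]]])$fractions
    mid[i, seq_along(f)] <- f
  }
  cbind(data.frame(metabolite = mets, turn = turn,
                   pool_nmol = unname(state$sizes[mets]),
                   stringsAsFactors = FALSE),
        as.data.frame(mid))
}

#' @export
print.label_timecourse <- function(x, ...) {
  cat(sprintf("<label time course> topology %s: %d metabolites, turns 0-%d\n",
              attr(x, "topology"), length(unique(x$metabolite)), max(x$turn)))
  NextMethod()
}

#' Plot the labeling trajectory of one metabolite
#'
#' @param x a `"label_timecourse"`.
#' @param metabolite which pool to plot.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted fraction matrix.
#' @export
plot.label_timecourse <- function(x, metabolite, ...) {
  metabolite <- canonical_metabolite(metabolite)
  sub <- x[x$metabolite == metabolite, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for ", metabolite)
  frac <- as.matrix(sub[, paste0("m", 0:7)])
  frac <- frac[, colSums(!is.na(frac)) > 0, drop = FALSE]
  graphics::matplot(sub$turn, frac, type = "b", pch = 19, lty = 1,
                    xlab = "turn", ylab = "isotopologue fraction",
                    main = metabolite, ...)
  graphics::legend("topright", legend = paste0("M+", seq_len(ncol(frac)) - 1),
                   col = seq_len(ncol(frac)), pch = 19, bty = "n")
  invisible(frac)
}

# ---- Monte-Carlo oracle -----------------------------------------------------

#' Monte-Carlo label propagation
#'
#' Simulates individual molecules as labeling bit patterns through the same
#' per-turn reaction semantics as [step_turn()]: each firing reaction builds
#' `round(m * n_molecules)` new product molecules from substrate molecules
#' sampled with replacement, replacing randomly chosen members of the product
#' pool; CO2 release/fixation is tracked as molecule counts. Serves as an
#' independent sampling-based check on the deterministic propagation.
#'
#' @param t a `"tf_topology"`.
#' @param init a [pool_state()] (pool sizes are ignored; label composition
#'   is used); defaults as in [simulate_labeling()].
#' @param cfg a [sim_config()] with `seed` and `n_molecules` set.
#' @return data frame with columns `metabolite`, `k` (mass shift),
#'   `fraction` (estimated MID component at the final turn) and `se`
#'   (binomial standard error).
#' @export
monte_carlo_labeling <- function(t, init = NULL, cfg) {
  stopifnot(inherits(t, "tf_topology"), !is.null(cfg$seed),
            !is.null(cfg$n_molecules), cfg$n_molecules >= 1000)
  if (is.null(init)) init <- pool_state(t, labeled = t$entry)
  set.seed(cfg$seed)
  nmol <- as.integer(cfg$n_molecules)
  m <- cfg$mixing_fraction
  r_recycle <- t$co2_policy$recycle_fraction
  pools <- lapply(init$dists, function(d) {
    sample.int(length(d$w), nmol, replace = TRUE, prob = d$w) - 1L
  })
  co2_total <- 0; co2_labeled <- 0
  ncarb <- metabolite_carbons(names(pools))
  revtab <- lapply(unique(ncarb), function(n) .revcode(0:(2^n - 1L), n))
  names(revtab) <- as.character(unique(ncarb))
  for (turn in seq_len(cfg$n_turns)) {
    start_pools <- pools
    contrib_sets <- list()  # mirrors step_turn's within-turn blending
    for (rxn in t$reactions) {
      k <- round(m * nmol)
      if (k < 1L) next
      q <- if (co2_total > 0) r_recycle * co2_labeled / co2_total else 0
      # sample substrate molecules per slot, with replacement
      sub_codes <- lapply(rxn$substrates, function(s)
        pools[[s]][sample.int(nmol, k, replace = TRUE)])
      getbit <- function(slot, carbon) {
        if (slot == 0L) stats::rbinom(k, 1L, q)
        else bitwAnd(bitwShiftR(sub_codes[[slot]], carbon - 1L), 1L)
      }
      new_codes <- vector("list", length(rxn$products))
      for (p in seq_along(rxn$products)) {
        map <- rxn$atom_map[[p]]
        code <- integer(k)
        for (i in seq_len(nrow(map))) {
          code <- code + getbit(map[i, 1L], map[i, 2L]) * 2L^(i - 1L)
        }
        met <- rxn$products[p]
        if (met %in% rxn$symmetric_products) {
          flip <- stats::runif(k) < 0.5
          rc <- revtab[[as.character(nrow(map))]]
          code[flip] <- rc[code[flip] + 1L]
        }
        new_codes[[p]] <- code
      }
      if (!is.null(rxn$losses)) {
        for (i in seq_len(nrow(rxn$losses))) {
          if (rxn$loss_to[i] == "co2") {
            bits <- getbit(rxn$losses[i, 1L], rxn$losses[i, 2L])
            co2_total <- co2_total + k
            co2_labeled <- co2_labeled + sum(bits)
          }
        }
      }
      for (met in unique(rxn$products)) {
        slots <- which(rxn$products == met)
        codes <- if (length(slots) == 1L) new_codes[[slots]] else {
          pick <- sample(slots, k, replace = TRUE)
          code <- integer(k)
          for (s in slots) code[pick == s] <- new_codes[[s]][pick == s]
          code
        }
        contrib_sets[[met]] <- c(contrib_sets[[met]], list(codes))
        j <- length(contrib_sets[[met]])
        src <- sample.int(j + 1L, nmol, replace = TRUE,
                          prob = c(1 - m, rep(m / j, j)))
        rebuilt <- start_pools[[met]]
        for (ci in seq_len(j)) {
          sel <- src == ci + 1L
          cs <- contrib_sets[[met]][[ci]]
          rebuilt[sel] <- cs[sample.int(length(cs), sum(sel), replace = TRUE)]
        }
        pools[[met]] <- rebuilt
      }
    }
  }
  out <- lapply(names(pools), function(met) {
    n <- ncarb[[met]]
    pc <- .popcount(pools[[met]])
    frac <- tabulate(pc + 1L, nbins = n + 1L) / nmol
    data.frame(metabolite = met, k = 0:n, fraction = frac,
               se = sqrt(pmax(frac * (1 - frac), 0) / nmol),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
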