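# Positional isotopomer distributions: probability vectors over the 2^n
# carbon-labeling patterns of an n-carbon metabolite. Pattern codes are
# integers 0..2^n-1; bit i-1 set means carbon i carries 13C.

.NORM_TOL <- 1e-9

#' Construct an isotopomer distribution
#'
#' @param metabolite canonical metabolite name (fixes the carbon count `n`).
#' @param weights numeric vector of length `2^n` over labeling patterns
#'   (pattern code `p` has carbon `i` labeled iff bit `i-1` of `p` is set);
#'   non-negative, summing to 1 (renormalized if within `1e-9`).
#' @return an object of class `"tf_isotopomer"` with fields `metabolite`,
#'   `n`, `w`.
#' @seealso [unlabeled_dist()], [fully_labeled_dist()], [collapse_to_mid()]
#' @export
isotopomer_dist <- function(metabolite, weights) {
  metabolite <- canonical_metabolite(metabolite)
  n <- unname(metabolite_carbons(metabolite))
  w <- as.numeric(weights)
  if (length(w) != 2^n) {
    stop(sprintf("%s has %d carbons: expected %d weights, got %d",
                 metabolite, n, 2^n, length(w)))
  }
  if (any(w < -.NORM_TOL)) stop("negative isotopomer weights")
  w[w < 0] <- 0
  s <- sum(w)
  if (abs(s - 1) > 1e-6) stop("isotopomer weights must sum to 1 (got ", s, ")")
  structure(list(metabolite = metabolite, n = n, w = w / s),
            class = "tf_isotopomer")
}

#' @rdname isotopomer_dist
#' @export
unlabeled_dist <- function(metabolite) {
  metabolite <- canonical_metabolite(metabolite)
  n <- unname(metabolite_carbons(metabolite))
  isotopomer_dist(metabolite, c(1, rep(0, 2^n - 1L)))
}

#' @rdname isotopomer_dist
#' @export
fully_labeled_dist <- function(metabolite) {
  metabolite <- canonical_metabolite(metabolite)
  n <- unname(metabolite_carbons(metabolite))
  isotopomer_dist(metabolite, c(rep(0, 2^n - 1L), 1))
}

#' @export
print.tf_isotopomer <- function(x, ...) {
  cat(sprintf("<isotopomer distribution> %s (%d carbons, %d patterns)\n",
              x$metabolite, x$n, length(x$w)))
  top <- order(x$w, decreasing = TRUE)
  top <- top[x$w[top] > 1e-6][seq_len(min(6L, sum(x$w > 1e-6)))]
  for (i in top) {
    pat <- paste(rev(as.integer(intToBits(i - 1L))[seq_len(x$n)]),
                 collapse = "")
    cat(sprintf("  %s  %.4f\n", pat, x$w[i]))
  }
  invisible(x)
}

# number of set bits for each element of an integer vector
.popcount <- function(x) {
  x <- as.integer(x)
  out <- integer(length(x))
  while (any(x > 0L)) {
    out <- out + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  out
}

# pattern code with carbon order reversed (2-fold rotational symmetry)
.revcode <- function(codes, n) {
  out <- integer(length(codes))
  for (i in seq_len(n)) {
    bit <- bitwAnd(bitwShiftR(as.integer(codes), i - 1L), 1L)
    out <- out + bit * 2L^(n - i)
  }
  out
}

.symmetrize_raw <- function(d) {
  perm <- .revcode(0:(2^d$n - 1L), d$n)
  d$w <- (d$w + d$w[perm + 1L]) / 2
  d
}

#' Symmetrize an isotopomer distribution
#'
#' Succinate and fumarate have 2-fold rotationally symmetric carbon
#' skeletons; their two orientations are chemically indistinguishable, so
#' each labeling pattern is averaged with its carbon-order-reversed partner.
#' The mass-isotopologue distribution (the popcount marginal) is unchanged.
#'
#' @param d a `"tf_isotopomer"` for a symmetric metabolite (`SUC`, `FUM`).
#' @return the symmetrized distribution.
#' @export
symmetrize <- function(d) {
  stopifnot(inherits(d, "tf_isotopomer"))
  if (!d$metabolite %in% .SYMMETRIC_METS) {
    stop(d$metabolite, " is not a symmetric metabolite")
  }
  .symmetrize_raw(d)
}

# ---- core propagation engine ------------------------------------------------

# Apply one reaction to substrate-slot distributions. Assumes substrate slots
# are independent (joint = product of marginals). CO2_IN entries draw a 13C
# with probability co2_q, modeled as an extra 1-carbon pseudo-substrate.
# Returns per-product-slot distributions (symmetrized where flagged), the
# labeled fraction of every lost carbon, and an expected-label audit.
.react <- function(dists, rxn, co2_q = 0) {
  if (length(dists) != length(rxn$substrates)) {
    stop("reaction ", rxn$name, " expects ", length(rxn$substrates),
         " substrate slot(s), got ", length(dists))
  }
  for (k in seq_along(dists)) {
    if (!inherits(dists[[k]], "tf_isotopomer") ||
        dists[[k]]$metabolite != rxn$substrates[k]) {
      stop("slot ", k, " of ", rxn$name, " requires ", rxn$substrates[k])
    }
  }
  work <- dists
  uses_co2 <- any(vapply(rxn$atom_map, function(m) any(m[, 1L] == 0L), TRUE))
  co2_slot <- 0L
  if (uses_co2) {
    co2_slot <- length(work) + 1L
    work[[co2_slot]] <- list(metabolite = ".CO2", n = 1L,
                             w = c(1 - co2_q, co2_q))
  }
  ns <- vapply(work, function(d) d$n, integer(1))
  off <- cumsum(c(0L, ns))[seq_along(ns)]
  N <- sum(ns)
  w <- work[[1L]]$w
  if (length(work) > 1L) {
    for (k in 2:length(work)) w <- as.vector(kronecker(work[[k]]$w, w))
  }
  jj <- 0:(2^N - 1L)
  srcbit <- function(slot, carbon) {
    s <- if (slot == 0L) co2_slot else slot
    bitwAnd(jj, bitwShiftL(1L, off[s] + carbon - 1L)) != 0L
  }
  products <- vector("list", length(rxn$products))
  n_co2_in <- 0L
  for (p in seq_along(rxn$products)) {
    m <- rxn$atom_map[[p]]
    nc <- nrow(m)
    code <- numeric(2^N)
    for (i in seq_len(nc)) {
      if (m[i, 1L] == 0L) n_co2_in <- n_co2_in + 1L
      code <- code + ifelse(srcbit(m[i, 1L], m[i, 2L]), 2^(i - 1L), 0)
    }
    wp <- numeric(2^nc)
    agg <- rowsum(w, code)
    wp[as.numeric(rownames(agg)) + 1L] <- agg[, 1L]
    d <- structure(list(metabolite = rxn$products[p], n = nc, w = wp / sum(wp)),
                   class = "tf_isotopomer")
    if (rxn$products[p] %in% rxn$symmetric_products) d <- .symmetrize_raw(d)
    products[[p]] <- d
  }
  loss_frac <- numeric(0)
  if (!is.null(rxn$losses)) {
    loss_frac <- vapply(seq_len(nrow(rxn$losses)), function(i) {
      if (rxn$losses[i, "carbon"] > ns[rxn$losses[i, "slot"]]) {
        stop("loss index out of range in ", rxn$name)
      }
      sum(w[srcbit(rxn$losses[i, "slot"], rxn$losses[i, "carbon"])])
    }, numeric(1))
  }
  label_in <- sum(vapply(dists, function(d) sum(d$w * .popcount(seq_along(d$w) - 1L)),
                         numeric(1))) + n_co2_in * co2_q
  label_out <- sum(vapply(products, function(d)
    sum(d$w * .popcount(seq_along(d$w) - 1L)), numeric(1))) + sum(loss_frac)
  list(products = products, loss_frac = loss_frac,
       loss_to = rxn$loss_to, n_co2_in = n_co2_in,
       audit = c(label_in = label_in, label_out = label_out))
}

#' Condense two substrates into one product
#'
#' Models a condensation such as citrate synthase (acetyl-CoA + oxaloacetate
#' -> citrate): the product's labeling distribution is the atom-map-directed
#' convolution of the two substrate distributions under the assumption that
#' substrate pools label independently.
#'
#' @param a,b `"tf_isotopomer"` distributions for the reaction's two
#'   substrate slots, in slot order.
#' @param r a two-substrate, one-product [reaction()].
#' @return the product `"tf_isotopomer"`.
#' @examples
#' tca <- build_topology("oxidative_tca")
#' cit <- condense(unlabeled_dist("OAA"), fully_labeled_dist("ACA"),
#'                 get_reaction(tca, "CS"))
#' collapse_to_mid(cit)  # all labeled mass at M+2
#' @export
condense <- function(a, b, r) {
  stopifnot(inherits(r, "tf_reaction"))
  if (length(r$substrates) != 2L || length(r$products) != 1L) {
    stop("condense() requires a reaction with two substrate slots and one product")
  }
  .react(list(a, b), r)$products[[1L]]
}

#' Transform a single substrate, tracking CO2 label
#'
#' Applies a one-substrate reaction (e.g. pyruvate decarboxylase): product
#' carbons are selected/permuted per the atom map, and for every carbon lost
#' to the CO2 pool the probability that it was labeled is reported.
#'
#' @param d substrate `"tf_isotopomer"`.
#' @param r a one-substrate [reaction()].
#' @param co2_q probability that a `CO2_IN` carbon (if the reaction fixes
#'   CO2, e.g. pyruvate carboxylase) is labeled.
#' @return list with `product` (`"tf_isotopomer"`; the first product slot),
#'   and `co2_label_fraction` (labeled fraction of CO2 released, `NA` when
#'   the reaction releases none).
#' @examples
#' gly <- build_topology("glycolysis")
#' out <- transform_dist(fully_labeled_dist("PYR"), get_reaction(gly, "PDC"))
#' out$co2_label_fraction  # 1: the lost carboxyl carbon was labeled
#' @export
transform_dist <- function(d, r, co2_q = 0) {
  stopifnot(inherits(r, "tf_reaction"))
  if (length(r$substrates) != 1L) {
    stop("transform_dist() requires a single-substrate reaction")
  }
  out <- .react(list(d), r, co2_q = co2_q)
  co2 <- out$loss_frac[out$loss_to == "co2"]
  list(product = out$products[[1L]],
       co2_label_fraction = if (length(co2)) mean(co2) else NA_real_)
}
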