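# Stoichiometric per-glucose ATP and cytosolic redox accounting for
# alternative metabolic strategies: pure fermentation, respiration without
# ETC complex I, triose diversion to glycerol-3-phosphate (the Gpd1 redox
# valve), and routing of glucose through the pentose phosphate shunt.

#' Configure a metabolic strategy
#'
#' @param respiring does the strategy oxidize non-fermented pyruvate through
#'   the TCA cycle and a complex-I-less electron transport chain?
#' @param atp_per_nadh ATP recovered per NADH at the ETC (default 1.0, the
#'   complex-I-less value; yeasts lacking proton-pumping complex I recover
#'   roughly one ATP per NADH).
#' @param atp_per_fadh2 ATP recovered per FADH2 (default 1.0).
#' @param slp_glycolysis net substrate-level ATP of glycolysis per glucose
#'   at zero diversion (fixed at 2 by the pathway's stoichiometry; exposed
#'   for transparency).
#' @param slp_tca substrate-level ATP/GTP at succinyl-CoA ligase per fully
#'   oxidized glucose (2).
#' @param g3p_diversion fraction `f` in `[0, 1]` of triose phosphate
#'   diverted to glycerol-3-phosphate by Gpd1 (consumes 1 cytosolic NADH per
#'   triose and forfeits its payoff ATP).
#' @param fermentation_fraction fraction of non-diverted triose-derived
#'   pyruvate reduced to ethanol (consumes 1 cytosolic NADH each); default 1
#'   for non-respiring strategies, 0 for respiring ones.
#' @param ppp_shunt_fraction fraction `s` of glucose routed through the
#'   oxidative + non-oxidative pentose phosphate shunt before re-entering
#'   glycolysis; each shunted glucose loses one carbon as CO2, so three
#'   shunted G6P return as five (not six) trioses.
#' @return a `"tf_strategy"` list.
#' @export
strategy_config <- function(respiring = FALSE,
                            atp_per_nadh = 1.0, atp_per_fadh2 = 1.0,
                            slp_glycolysis = 2, slp_tca = 2,
                            g3p_diversion = 0,
                            fermentation_fraction = if (respiring) 0 else 1,
                            ppp_shunt_fraction = 0) {
  stopifnot(atp_per_nadh >= 0, atp_per_fadh2 >= 0,
            g3p_diversion >= 0, g3p_diversion <= 1,
            fermentation_fraction >= 0, fermentation_fraction <= 1,
            ppp_shunt_fraction >= 0, ppp_shunt_fraction <= 1)
  structure(list(respiring = respiring,
                 atp_per_nadh = atp_per_nadh, atp_per_fadh2 = atp_per_fadh2,
                 slp_glycolysis = slp_glycolysis, slp_tca = slp_tca,
                 g3p_diversion = g3p_diversion,
                 fermentation_fraction = fermentation_fraction,
                 ppp_shunt_fraction = ppp_shunt_fraction),
            class = "tf_strategy")
}

# trioses reaching lower glycolysis per glucose: 2 for the direct route,
# 5/3 for glucose routed via the PPP shunt (one CO2 lost per shunted G6P)
.trioses_per_glucose <- function(cfg) {
  2 * (1 - cfg$ppp_shunt_fraction) + (5 / 3) * cfg$ppp_shunt_fraction
}

.budget <- function(cfg) {
  stopifnot(inherits(cfg, "tf_strategy"))
  f <- cfg$g3p_diversion
  ff <- cfg$fermentation_fraction
  T_ <- .trioses_per_glucose(cfg)
  if (f > T_) stop("g3p_diversion exceeds available trioses per glucose")
  # ATP: invest 1 at hexokinase per glucose + 1 at PFK per hexose reaching
  # lower glycolysis; payoff 2 (PGK + PK) per non-diverted triose
  atp_consumed <- T_                       # equals the investment phase cost
  atp_produced <- 2 * (T_ - f)
  nadh_produced <- T_ - f                  # GAPDH, cytosolic
  nadh_consumed <- f + ff * (T_ - f)       # Gpd1 + alcohol dehydrogenase
  if (cfg$respiring) {
    # glucose-equivalents fully oxidized: non-diverted, non-fermented trioses
    ox <- (1 - ff) * (T_ - f) / 2
    atp_produced <- atp_produced +
      ox * (cfg$slp_tca + 10 * cfg$atp_per_nadh + 2 * cfg$atp_per_fadh2)
  }
  structure(list(atp_produced = atp_produced, atp_consumed = atp_consumed,
                 atp_net = atp_produced - atp_consumed,
                 nadh_produced = nadh_produced, nadh_consumed = nadh_consumed,
                 nadh_net = nadh_produced - nadh_consumed,
                 strategy = cfg),
            class = "energy_budget")
}

#' Per-glucose ATP budget of a metabolic strategy
#'
#' Glycolysis alone nets 2 ATP per glucose (invest 2, recover 2 per triose).
#' Diverting a fraction `f` of triose phosphate to glycerol-3-phosphate
#' forfeits its payoff: `atp_net = 2 (2 - f) - 2` for a fermentative
#' strategy. A respiring strategy additionally recovers, per fully oxidized
#' glucose, 2 substrate-level ATP at succinyl-CoA ligase plus the ETC yield
#' of 10 NADH and 2 FADH2; at the complex-I-less defaults this totals 16 ATP
#' per glucose.
#'
#' @param cfg a [strategy_config()].
#' @return an `"energy_budget"` with ATP and NADH production, consumption
#'   and net fields (per glucose; NADH fields are the cytosolic ledger of
#'   [redox_balance()]).
#' @examples
#' atp_yield(strategy_config())                   # fermentation: net 2
#' atp_yield(strategy_config(respiring = TRUE))   # full oxidation: net 16
#' @export
atp_yield <- function(cfg) .budget(cfg)

#' Cytosolic NADH balance of a metabolic strategy
#'
#' GAPDH produces one cytosolic NADH per non-diverted triose; Gpd1 consumes
#' one per diverted triose; alcohol dehydrogenase consumes one per fermented
#' pyruvate. Pure fermentation (`f = 0`, `fermentation_fraction = 1`) is
#' redox-neutral.
#'
#' @param cfg a [strategy_config()].
#' @return an `"energy_budget"` (see [atp_yield()]); the NADH fields carry
#'   the cytosolic ledger.
#' @export
redox_balance <- function(cfg) .budget(cfg)

#' Fermentation fraction restoring cytosolic redox balance
#'
#' Solves `(T - f) - f - x (T - f) = 0` for the fermentation fraction `x`,
#' where `T` is the trioses reaching lower glycolysis per glucose (2 without
#' a PPP shunt) and `f` the Gpd1 diversion; the closed form
#' `x = (T - 2 f) / (T - f)` is clipped to `[0, 1]`.
#'
#' @param cfg a [strategy_config()]; its `fermentation_fraction` is ignored.
#' @return the balancing fermentation fraction.
#' @examples
#' balance_fermentation(strategy_config(g3p_diversion = 0.5))  # 2/3
#' @export
balance_fermentation <- function(cfg) {
  stopifnot(inherits(cfg, "tf_strategy"))
  T_ <- .trioses_per_glucose(cfg)
  f <- cfg$g3p_diversion
  if (f >= T_) stop("g3p_diversion must be below trioses per glucose")
  min(1, max(0, (T_ - 2 * f) / (T_ - f)))
}

#' @export
print.energy_budget <- function(x, ...) {
  s <- x$strategy
  cat("<energy budget> per glucose,",
      if (s$respiring) "respiring (complex-I-less ETC)" else "non-respiring",
      "\n")
  cat(sprintf("  G3P diversion f = %.2f, fermentation fraction = %.2f, PPP shunt = %.2f\n",
              s$g3p_diversion, s$fermentation_fraction, s$ppp_shunt_fraction))
  cat(sprintf("  ATP : produced %.3f, consumed %.3f, net %+.3f\n",
              x$atp_produced, x$atp_consumed, x$atp_net))
  cat(sprintf("  NADH: produced %.3f, consumed %.3f, net %+.3f (cytosolic)\n",
              x$nadh_produced, x$nadh_consumed, x$nadh_net))
  invisible(x)
}
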