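---
title: "Positional 13C label propagation and isotopologue diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional 13C label propagation and isotopologue diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracefate)
```

## The scientific problem

When cells are switched onto uniformly labeled ^13^C~6~-glucose, the tracer
spreads through central carbon metabolism along routes fixed by the carbon
skeletons of the intervening reactions. Sampling metabolite pools by GC-MS
shortly after the switch yields, for each metabolite, a mass-isotopologue
distribution (MID): the fractions of the pool carrying 0, 1, ..., n heavy
carbons (M+0..M+n). Because alternative pathway architectures route carbon
differently, specific isotopologues act as diagnostics. For the TCA
pathway:

* a single oxidative turn condenses M+2 acetyl-CoA with M+0 oxaloacetate
  and, after two decarboxylations that remove oxaloacetate-derived carbons,
  leaves **M+2 fumarate**;
* the reductive branch carboxylates M+3 pyruvate with unlabeled CO~2~ and
  reduces the resulting oxaloacetate to **M+3 fumarate**;
* repeated oxidative turns, which return labeled carbon to oxaloacetate,
  build up **M+4 fumarate**;
* carboxylation of M+3 pyruvate with ^13^C-bicarbonate released by earlier
  decarboxylations (endogenous recycling) produces **M+4
  oxaloacetate/aspartate**, so M+4 species are not an unambiguous signature
  of a closed oxidative cycle.

`tracefate` turns this qualitative reasoning into a tested computational
pipeline: an atom-map-level label propagation engine, MID analysis and
natural-abundance correction, internal-standard quantification of GC-MS
integrals, a scoring scheme that ranks candidate TCA architectures against
observed diagnostics, stoichiometric ATP/redox budgets for the metabolic
strategies being compared, and synthetic-data generators that make the whole
pipeline testable end to end.

## The propagation model

**State.** Every metabolite pool carries a positional isotopomer
distribution: a probability vector over the $2^n$ labeling patterns of its
$n$ tracked backbone carbons ($n \le 7$; at this scale full enumeration is
cheap and, unlike MID-only bookkeeping, positional tracking is required to
decide *which* carbon a decarboxylation removes). The popcount marginal of
this vector is the MID.

**Reactions.** Each reaction declares an explicit atom map: the origin of
every product carbon (a substrate slot/position or the CO~2~ pool) and the
fate of every substrate carbon not incorporated (released to the CO~2~ pool
or discarded). Validation checks carbon conservation per reaction.
Condensations assume substrate pools label independently, the standard
assumption in isotopomer simulation absent covariance information.
Succinate and fumarate, whose skeletons have 2-fold rotational symmetry,
are symmetrized on production (each pattern averaged with its reversed
pattern), which never changes an MID.

**Turns.** A topology is an ordered reaction list applied once per *turn*,
the discrete counterpart of a TCA "cycle". Within a turn, reactions fire
sequentially and read the partially updated state, so one turn carries
acetyl label all the way to fumarate — matching how the first "cycle" is
usually drawn. Each firing replaces a fraction $m$ (the *mixing fraction*)
of its product pool; when several reactions feed the same pool in one turn
(both TCA branches producing succinate, say), their contributions blend
with equal weight rather than overwriting each other. $m = 1$ gives the
idealized fully-turned-over pool; $m < 1$ leaves pre-existing material in
place, as in a pre-steady-state time course. Mapping turns to minutes is
deliberately left to the user: the underlying experiments provide no rate
constants, so the package treats the turn index as ordinal time.

**CO~2~ pool.** Decarboxylations deposit CO~2~ into a single well-mixed
internal pool tracked as cumulative released moles and their labeled
fraction (a running mixture). A carboxylation draws its fixed carbon from
this pool with probability `recycle_fraction` $\in [0,1]$ and from an
infinite unlabeled external reservoir otherwise. This is the minimal model
sufficient for the bicarbonate-recycling argument; it does not model CO~2~
escape kinetics or compartment-specific pools. Because substrate pools are
not depleted (they stand for flux-replenished steady-state pools), global
label totals are not conserved turn-by-turn in open networks; conservation
is instead guaranteed — and tested — at the level of every single reaction
application (expected label in = expected label out), and holds globally at
the fixed point of closed cycles.

**Verification.** A molecule-level Monte-Carlo simulator implements the
same semantics by propagating individual label bit-vectors and serves as an
independent oracle: for every preset, deterministic MIDs agree with the
sampling estimates within four binomial standard errors at $10^5$
molecules.

## Topology presets

* `glycolysis` — hexokinase through pyruvate kinase with the canonical
  aldolase/triose-phosphate-isomerase carbon split, plus the fermentative
  tail (pyruvate decarboxylase, alcohol dehydrogenase).
* `oxidative_tca` — pyruvate dehydrogenase, citrate synthase, aconitase,
  isocitrate dehydrogenase, a lumped alpha-ketoglutarate
  dehydrogenase/succinyl-CoA ligase step, succinate dehydrogenase
  (omittable with `include_sdh = FALSE`), fumarase, malate dehydrogenase.
  The atom maps encode aconitase stereospecificity: both first-turn CO~2~
  losses remove oxaloacetate-derived carbons, which is the only routing
  consistent with first-turn M+2 fumarate.
* `reductive_branch` — pyruvate carboxylase (CO~2~ fixed into the C4
  carboxyl, the standard flux-analysis convention; MID-level results do not
  depend on which terminal carboxyl is chosen), malate dehydrogenase and
  fumarase run in reverse, fumarate reductase (omittable).
* `bifurcated_tca` — the union of the two branches with no succinate
  dehydrogenase step; its default `recycle_fraction` of 0.5 reflects that
  endogenous bicarbonate recycling is this architecture's signature
  (without it the preset is observationally the reductive branch plus an
  oxidative stub), while the other presets default to 0. The relative flux
  weighting of the two branches is not specified by the biology this
  package draws on; the reaction order gives them equal per-turn weight and
  users can adjust pool sizes or build custom topologies to explore
  imbalance.
* `ppp_shunt` — glucose-6-phosphate dehydrogenase, 6-phosphogluconate
  dehydrogenase (the oxidative CO~2~ loss), and the non-oxidative
  recombination 3 C5 &rarr; 2 C6 + 1 C3 as one lumped carbon-balanced block
  with the canonical transketolase/transaldolase atom routing. The branch
  is treated as a shunt back into glycolysis, not reaction by reaction.

Reversibility is not modeled: each preset is a directed per-turn order,
which is what the qualitative per-cycle isotopologue logic assumes.

## MID analysis

Fractional labeling is defined as $1 - \mathrm{M{+}0}$, a molecule-level
fraction ("share of the pool containing any tracer carbon"), not the
carbon-weighted mean enrichment. Multiplying by the pool size gives the
nmol of labeled metabolite; dividing by elapsed time gives a synthesis rate
when the caller picks a point in the initial linear window — for fast pools
such as glycerol-3-phosphate that is the earliest sampled point.

Natural-abundance correction models the tracked backbone carbons only
(derivatization and silyl atoms are outside scope) with default
$p_{13} = 0.0107$. The correction solves the lower-triangular binomial
system by forward substitution, clamping each component at zero as it is
computed: on exact forward-convolved input the clamp never engages and the
round trip is exact to numerical precision, while on noisy input the clamp
suppresses the sign-oscillating artifacts that plain solve-then-clip
produces. Correction is **off by default** for simulator output, which is
tracer-pure by construction.

## Architecture inference

`predict_diagnostics()` simulates a candidate from its fully labeled tracer
entry and calls each of eight diagnostics (fumarate M+2/3/4, succinate
M+2/3/4, aspartate M+3/4, with aspartate read from oxaloacetate when not
modeled separately) *expected present* if its fraction exceeds a detection
threshold $\theta$ at any recorded turn — a time-course maximum, because
the informative isotopologues are transient. $\theta$ defaults to 0.01 of
the pool: presence calls in this field are read off bar plots, and a small
fixed, configurable threshold is the honest formalization of that practice.
`infer_topologies()` scores candidates by the fraction of diagnostics whose
predicted and observed calls agree — a matching count, not a likelihood,
because no noise model for MID fractions is available and inventing one
would add structure the data cannot support. Ties break by parsimony
(fewer predicted-present diagnostics), then by name, making the ranking
deterministic; candidates with identical predicted calls are reported as
observationally equivalent rather than silently ordered. One observation
the scoring deliberately does not model: respiro-fermenting cells can show
M+4 succinate without M+3, suggesting fumarate-reductase preference among
fumarate isotopologues, possibly reflecting compartmentalized fumarate
pools; with no compartment model available this is left unscored.

## Energy and redox budgets

The ATP ledger is stoichiometric, not kinetic. Glycolysis invests 2 ATP per
glucose and recovers 2 per triose, netting 2; diverting a fraction $f$ of
triose phosphate to glycerol-3-phosphate (the Gpd1 redox valve) forfeits
that payoff, netting $2(2-f) - 2$. A respiring strategy adds, per fully
oxidized glucose, 2 substrate-level ATP plus the ETC yield of 10 NADH and
2 FADH~2~. The defaults `atp_per_nadh = atp_per_fadh2 = 1.0` are one
consistent choice for a complex-I-less chain, landing complete oxidation at
16 ATP/glucose — inside the 16–18 range usually cited for such yeasts,
whose exact assumptions vary by source; both parameters are exposed. The
cytosolic redox ledger counts GAPDH production $(2-f)$ against Gpd1 ($f$)
and alcohol dehydrogenase (fermentation fraction $\times (2-f)$)
consumption; `balance_fermentation()` returns the closed-form fermentation
fraction $(2-2f)/(2-f)$ that zeroes it. Routing a fraction of glucose
through the pentose phosphate shunt is modeled purely as carbon returned at
the triose level (three shunted hexoses return five trioses, one CO~2~ lost
each); NADPH accounting, proton-motive force and growth-rate prediction are
out of scope. Mitochondrial and cytosolic NADH pools are not separated
except in the explicitly cytosolic redox ledger, matching the granularity
of the underlying argument.

## Synthetic data: what it does and does not emulate

The generators produce inputs with the statistical structure the analysis
assumes, with known ground truth:

* **Integral tables** — `integral = MRRF × nmol / SI_nmol × SI_integral ×
  noise` with a 1 nmol scyllo-inositol internal standard per sample,
  multiplicative log-normal noise (unit mean, configurable CV; GC-MS
  intensity noise is approximately proportional, and no more specific noise
  model is available), a noise-free standard mix from the same response
  factors, and a default layout of six replicate samples. Default true
  abundances and response factors are a fixed, realistic central-carbon
  panel (tenths of nmol to a few nmol per sample).
* **Label time courses** — deterministic simulation under a chosen preset,
  optional natural-abundance forward convolution, multiplicative noise per
  MID component with renormalization, four-replicate-style noise levels.
* **Growth/glucose series** — exponential OD with consistent glucose
  depletion, constructed so the uptake-rate formula recovers the embedded
  rate exactly at zero noise.

Passing the recovery suites therefore shows that the pipeline is correct
and robust to proportional intensity noise at realistic magnitudes. It does
not show robustness to what the generators deliberately omit: peak
integration and retention-time errors, fragment-specific MIDs,
derivatization-atom isotope effects, correlated (batch) noise, or
compartment-mixed pools. Conclusions about real chromatograms still require
the upstream integration software to have done its job.

## Numerical choices and degenerate inputs

Isotopomer and MID vectors are validated to sum to 1 within $10^{-9}$ and
renormalized after every operation. Division by zero in diagnostic ratios
yields `NA`, never an error; missing metabolites yield absent ratios.
Metabolites present in samples but absent from the standard mix are
reported relative to the internal standard and flagged `unquantified`
rather than silently dropped or given invented response factors. The
zero-label state is verified to be a fixed point. Problem sizes throughout
the test suite — $\le 2^{15}$ joint states per reaction, $10^5$ Monte-Carlo
molecules, 100-seed recovery experiments, six-turn simulations — were
chosen as the smallest sizes at which the statistical assertions are
well-powered, and the full suite runs in well under a minute.

## Known limitations

* No flux estimation: the package reasons about architecture
  (presence/absence), not flux magnitudes; no ^13^C-MFA fitting.
* No reversible exchange fluxes and no compartmentation; the
  fumarate-isotopologue compartment effect noted above is surfaced but not
  modeled.
* Natural abundance is applied only at the MID level for backbone carbons;
  fragment-level (mass-spectral fragment) handling is excluded.
* The turn index is ordinal; quantitative time-course fitting would require
  rate constants the package does not estimate.
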