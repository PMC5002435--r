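---
title: "Methods: constraint-based analysis of glucosylglycerol salvage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based analysis of glucosylglycerol salvage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggflux)
```

## The biological question

*Synechocystis* sp. PCC 6803 accumulates glucosylglycerol (GG) as its main
osmolyte under salt stress. Making one GG molecule costs the cell nine fixed
carbons plus the energy of the synthesis pathway, yet the compound is often
needed only transiently. A salvage route — cleaving GG back into a glucose
moiety and glycerol once osmotic protection is no longer required — would
let the cell recover that investment. The GHL5-family protein Slr1670 is the
candidate cleavage enzyme: its inactivation abolishes glycerol formation
from GG and raises intracellular GG levels.

`ggflux` asks the quantitative follow-up questions with flux balance
analysis (FBA):

1. How much faster can a cell grow if it can re-assimilate GG supplied at a
   measured specific rate $q_{GG}$?
2. Does the cleavage chemistry matter — phosphorolysis (yielding
   glucose-1-phosphate, sparing one ATP) versus hydrolysis (yielding free
   glucose, which must be phosphorylated by glucokinase)?
3. Is re-assimilating the glycerol moiety (via glycerol kinase, GlpK) worth
   anything?

## The model and its assumptions

FBA treats metabolism as a stoichiometric matrix $S$ (metabolites x
reactions) at steady state. A flux vector $v$ is feasible when

$$ S\,v = 0, \qquad lb \le v \le ub , $$

and the predicted growth rate is the maximum of the biomass objective
("BOFmax") over that polytope. Fluxes are in mmol gDW$^{-1}$ h$^{-1}$; the
biomass flux is in h$^{-1}$. The usual FBA caveats apply: no kinetics, no
regulation, growth-optimality assumed.

### The salvage extension

A base reconstruction knows how to synthesize GG but gives the degradation
route no path to carry flux. `gg_extension_specs()` therefore adds seven
reactions (`extend_with_gg()` skips any whose id a full reconstruction
already carries):

| id | reaction | why |
|---|---|---|
| `EX_glcglyc(e)` | `glcglyc_e =>` | boundary exchange; uptake is negative flux |
| `GLCGLYCtex` | `glcglyc_e <=> glcglyc_p` | outer-membrane transport |
| `GLCGLYCABCpp` | `glcglyc_p => glcglyc_c` | GgtABCD re-uptake |
| `glcglyctpp` | `glcglyc_c => glcglyc_p` | diffusive leakage out of the cytosol |
| `GLCGLYCstorage` | `glcglyc_c =>` (sink) | steady-state stand-in for accumulation |
| `GLCGLYCHyd` | `h2o_c + glcglyc_c => glc__D_c + glyc_c` | hydrolysis (*slr1670*) |
| `GLCGLYCPhosphorylase` | `pi_c + glcglyc_c => g1p_c + glyc_c` | phosphorolysis (*slr1670*) |

The storage sink is the key modelling trick: an FBA model maximizing growth
would never synthesize an osmolyte (it is pure cost), and a model forced to
take GG up could not reach steady state if nothing consumed it. The sink
absorbs GG without rewarding it, so "GG is available but may go unused" is
representable. It is irreversible with an unbounded upper limit and no
biomass contribution.

The ABC uptake step is shipped as a plain irreversible periplasm-to-cytosol
transport without an explicit ATP coupling, since no stoichiometry beyond
the reaction name is published for it; a reconstruction that already
contains an ATP-coupled version keeps its own copy (`add_if_absent`).
Directionality follows the leakage/re-uptake narrative: leakage strictly
cytosol to periplasm, ABC uptake strictly periplasm to cytosol.

### Fitness ratios

The benefit of a utilization route is quantified as

$$ \mathrm{ratio} = 100 \times
   \frac{\mathrm{BOFmax}(\text{route free},\ [0, \infty))}
        {\mathrm{BOFmax}(\text{route fixed to } 0)} , $$

with the GG supply fixed at $q_{GG}$ as an *equality* in both numerator and
denominator. Supply can be routed through the exchange (exogenous GG, the
default, matching cultures fed GG — the condition from which the measured
$q_{GG}$ values derive) or through the synthesis reaction (endogenous GG
under salt); both are exposed because the published description is
compatible with either. `simulate_table5()` applies this per culture
interval and strain, dividing each strain's BOFmax by that of the
cleavage-deficient *slr1670* mutant; the default interval table carries the
five measured rates (0.008, 0.015, 0.014, 0.009, 0.003 mmol gDW$^{-1}$
h$^{-1}$). Whether hydrolysis, phosphorolysis, or both may carry flux is a
`cleavage` argument, not a hard-coded choice.

### Strains

Knockouts are bound constraints ($lb = ub = 0$). Both cleavage reactions are
associated with *slr1670*, so `dslr1670` silences the pair, and
`dglpK_dslr1670` is the union of the single mutants. Knocking out the
objective is refused.

## Culture arithmetic

From OD$_{730}$/glycerol time series the package computes, per replicate:

* $\mu = \ln(OD(t_1)/OD(t_0)) / (t_1 - t_0)$ (d$^{-1}$); endpoints are
  log-linearly interpolated when not sampled exactly. Negative rates are
  reported as-is and flagged non-physical in ratios — a growth-only model
  cannot match them, but hiding them would misrepresent the data.
* $q_{GG} = \Delta[\mathrm{glycerol}] / (\bar{X} \, \Delta t)$ with
  $\bar{X}$ the biomass concentration (gDW/L) from OD at 0.2 g/L per OD
  unit and $\Delta t$ in hours. One glycerol is released per GG cleaved, so
  in a synthesis-deficient strain fed GG the extracellular glycerol curve
  counts cleavage events. $\bar{X}$ uses the time-weighted trapezoidal mean
  OD over the interval (endpoint averaging is available as an option); the
  published description does not fix the averaging, and the trapezoid is
  the natural discretization of $\int X\,dt$. A glycerol *decrease* yields
  $q_{GG} = 0$ with a warning, since re-uptake of glycerol is outside the
  model.
* Intracellular concentrations use 0.2 gDW/L per OD$_{730}$ unit and 1 µL
  intracellular volume per mg dry weight.
* Strain-to-reference ratios are computed for every pairing of strain and
  reference replicates and summarized as mean ± sd, so the uncertainty of
  both strains propagates.

## The synthetic data

### Toy model

`toy_model()` is a ~24-reaction photoautotroph whose optima are derivable
by hand: photons convert to ATP 1:1 (bounded by `photon_bound`, default
$P = 100$), carbon fixation costs 2 ATP per CH$_2$O unit, and one biomass
unit costs 1 CH$_2$O + 1 ATP, so $\mathrm{BOFmax} = P/3$ without GG. GG
synthesis costs 9 CH$_2$O + 1 ATP; cleavage returns the carbons — the
glucose moiety worth 6 CH$_2$O (free after phosphorolysis, one glucokinase
ATP after hydrolysis) and the glycerol moiety worth 3 CH$_2$O for one
glycerol-kinase ATP. With exogenous GG fixed at $q$:

$$ \mathrm{BOFmax} = \frac{P + 17q}{3} \ \text{(phosphorolysis + GlpK)},
   \quad \frac{P + 16q}{3} \ \text{(hydrolysis + GlpK)},
   \quad \frac{P + 12q}{3} \ \text{(GlpK blocked)} . $$

All coefficients are small integers so these optima are exact; the test
suite freezes them and also cross-checks the solver against an independent
vertex-enumeration oracle on random models. The toy model reproduces the
*direction* of the genome-scale predictions (phosphorolysis preferred,
glycerol salvage a small extra, benefit vanishing as $q_{GG} \to 0$) but
deliberately exaggerates their *size*: a real reconstruction has hundreds
of alternative routes that dilute the marginal value of nine carbons, the
toy model has none. Passing tests therefore validate the machinery and the
qualitative biology, not the genome-scale percentages; those require the
published reconstruction, which the pipeline accepts via
`read_metabolic_model()` in either BiGG JSON or SBML L3/fbc.

### Culture simulator

`simulate_culture()` emulates the batch experiments: exponential OD growth
from `od0` at `mu_true` (default 0.6 d$^{-1}$, an OD doubling time of about
28 h, typical for these cultures) switching to linear growth above
`od_linear` (default 1.5) where self-shading makes light, not biomass, the
limiting resource; glycerol accumulating as
$q_{GG} \cdot 24 \cdot 0.2 \cdot \int OD\,dt$; and multiplicative
log-normal noise (measurements are positive), 2% on OD and 5% on glycerol
by default — of the order of the replicate scatter such experiments show,
not a fitted claim. The seed is mandatory and the caller's RNG state is
restored, so identical seeds give bitwise-identical series. What the
simulator does *not* emulate: the transient OD drop seen in
cleavage-proficient strains around day 8 (its cause is unknown), glycerol
re-uptake, and day/night cycling. Parameter recovery on these simulations
(the acceptance suite uses 200 cultures, $q_{GG} \in [0.003, 0.015]$,
intervals within the exponential phase) shows the estimator works on data
the generator's assumptions describe; it cannot certify behaviour on
effects the generator omits.

## Numerical choices

* **LP engine.** A dense two-phase tableau simplex with Bland's rule,
  written for this package. FBA problems are massively degenerate, and
  Bland's rule guarantees termination; dense tableaus are exact to
  elimination round-off and entirely adequate at these sizes (tens to a
  few thousand reactions). Primal feasibility is enforced to $10^{-9}$;
  phase-1 infeasibility above $10^{-7}$ reports `infeasible`.
* **Infinite bounds** are capped at $10^{5}$ mmol gDW$^{-1}$ h$^{-1}$
  inside the solver; an optimum pinned to the cap on a nominally unbounded
  reaction is reported `unbounded`.
* **Exact ratios.** Reported ratios of two optima remove float noise by
  theorem, never by rounding: when one problem's feasible set contains the
  other's, $\mathrm{BOFmax}$ is clamped to the implied inequality; and when
  each optimum carries (numerically) zero flux through every reaction that
  distinguishes the two problems, the optima are provably equal and the
  ratio is exactly 100. This is why `fitness_ratio(qGG = 0)` is `100`
  exactly rather than `100 ± 1e-13`. Ratios are otherwise *not* rounded;
  round to one decimal for display if table-style output is wanted.
* **Degenerate optima.** Only the objective value is contractual. Flux
  vectors are returned for inspection but alternate optima exist; tests
  assert objective values and forced zeros only.
* **Units.** Fluxes mmol gDW$^{-1}$ h$^{-1}$; biomass h$^{-1}$; culture
  time in days, converted at 24 h/day inside `estimate_qGG()`.
* **Default bounds** when a file omits them: -1000/1000 (reversible),
  0/1000 (irreversible), the convention of the BiGG model family.
* **Ids.** Canonical BiGG spellings internally (`EX_glcglyc(e)`,
  `glc__D_c`); SBML escaping (`R_`/`M_`, `_DASH_`, `_LPAREN_`, `_RPAREN_`)
  applied only at serialization. Upper-cased exchange stems from legacy
  exports are folded to lower case on read.

## Worked example

```{r example, eval = FALSE}
tm <- toy_model(photon_bound = 100)
solve_fba(tm)$objective_value     # 33.3333 = P/3
fitness_ratio(tm, qGG = 0.008)    # 100.136 = 100 (1 + 17 q / P)
simulate_table5(tm)               # per-interval strain ratios
autoplot(sweep_cleavage_modes(tm))

d <- simulate_culture(seed = 1)
growth_rate(d, c(0, 2))
estimate_qGG(d, c(0, 4))
```

## Known limitations

* The photon uptake flux equivalent to the experimental 30 µE m$^{-2}$
  s$^{-1}$ is not published as a flux; full-scale runs must set
  `photon_bound` from their model's own calibration (the pipeline records
  it, plus the model file's checksum, in the run manifest rather than
  assuming a value).
* Constant photon uptake over a batch culture underestimates the relative
  benefit of GG salvage at high culture densities, where growth is
  light-limited; the per-interval ratios at late time points inherit this.
* No flux variability analysis, MOMA, dynamic FBA or thermodynamic
  consistency checks; gene associations are stored as strings, not
  evaluated as boolean rules.
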