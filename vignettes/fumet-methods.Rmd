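---
title: "Modeling 5-fluorouracil metabolism under ATP depletion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 5-fluorouracil metabolism under ATP depletion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fumet)
```

# The system and the model

5-fluorouracil (5-FU) is a fluorinated pyrimidine prodrug. In budding yeast
it is metabolized through the nucleotide salvage pathways into fluorinated
nucleosides, mono-/di-/triphosphates and, through the triphosphates, into
RNA and DNA. Because yeast lacks thymidine phosphorylase and thymidine
kinase, the route to the thymidylate-synthase inhibitor FdUMP runs through
the diphosphate pool, which makes the cellular ATP status — and its collapse
under oxidative stress — a potential switch between anabolic and catabolic
processing of the drug.

`fumet` implements a kinetic model of this system: 16 species (14
fluorinated pools plus ATP and ADP) coupled by 22 enzymatic reactions, each
bound to one of three rate laws:

* irreversible Michaelis–Menten, $v = V S/(K_m+S)$ (13 reactions),
* reversible Michaelis–Menten,
  $v = (V_f S/K_{ms} - V_r P/K_{mp}) / (1 + S/K_{ms} + P/K_{mp})$
  (2 reactions), and
* reversible Ping Pong Bi Bi in Cleland's form (7 kinase reactions, each
  consuming ATP and producing ADP 1:1).

Every reaction converts exactly one fluorinated species into exactly one
fluorinated species, so the fluorinated indicator vector is a left null
vector of the stoichiometry matrix and total fluorine is structurally
conserved — the package's most important invariant, mirrored by the
experimental observation that the summed ¹⁹F signal stays constant.

The exact algebraic Ping Pong Bi Bi form used by the original analysis is
not stated; we adopt the Cleland reversible form whose parameter list
{`Keq`, `Kia`, `Kiq`, `Kma`, `Kmb`, `Kmp`, `Kmq`, `Vf`, `Vr`} is in
one-to-one correspondence with the published parameter table and is the
form used by common biochemical-network simulators. This is a design
decision, not a fact recovered from the source.

Units are µM and hours throughout.

## Parameter registry

Published best-fit values ship as defaults. The registry enforces the
published constraints by construction:

* sharing: reactions 11 and 18 share the nucleoside-diphosphate kinase
  parameters of reaction 3; 15 shares 7; 20 shares 13; 21 shares 5; 22
  shares 6; and the V of reaction 6 is linked to reaction 5. Shared values
  are stored once, so `setParameter()` on one member changes all of them.
* fixing: the phosphohydrolase Michaelis constants are fixed at 15 µM
  (UTP/dTTP analogues) and 12.5 µM (UDP/dTDP analogues) and are excluded
  from every fit.

Counting 16 initial concentrations plus the nominal per-reaction
complements (2/4/9 by law) gives 113 parameters; removing the 34 duplicates
introduced by sharing and the 2 fixed constants leaves 77 free.

Two table cells in the published parameter listing are visibly garbled
(blank cells in reactions 13 and 17 with stray value rows at the block
ends). We resolved the alignment by cross-validating |bfv−avg|/stds against
the printed dev/stds column, which identifies a one-row downward shift of
the value columns; the restored assignment (e.g. $V_f = 3173.8$,
$V_r = 81.19$ for the hypothetical polyribonucleotide transferase) also
gives the physically sensible picture of fluorinated RNA being degraded
toward the diphosphate pool. These entries remain low-confidence.

## Initial state

The supplementary table of fitted initial concentrations is not available
in the source we work from. The shipped default initial state is therefore
*synthetic*: it places the 1 mM (1000 µM) total fluorine predominantly in
the di-/triphosphate and nucleic-acid pools, qualitatively matching the
reported distribution an hour into the experiment, and is documented as
such. Every value can be overridden via `buildNetwork(initial = ...)` or a
configuration file.

# ATP handling

The experiment tracks relative ATP by ³¹P NMR: ATP(0) ≡ 1, halved within
about an hour, near zero by 4 h, never recovering. The functional form of
the fitted ATP catabolism curve is not stated, so the package provides two
modes:

* **forced** (default): ATP follows the monotone decay
  $ATP_{rel}(t) = 1/(1+(t/t_{50})^s)$ with $t_{50} = 1$ h and $s = 2.2$,
  chosen so the level is 0.5 at 1 h and below 0.05 at 4 h; ADP complements
  the adenylate pool. The curve is a documented guess at an unstated fit.
* **dynamic**: ATP/ADP are state variables and a first-order ATP→ADP sink
  (default 0.8 h⁻¹) emulates bulk non-fluorinated ATPase activity. The sink
  is boundary-condition plumbing, not a reaction of the metabolic network;
  with the sink off, ATP+ADP is conserved exactly.

# Simulation and steady states

Trajectories integrate $\dot x = S\,v(x)$ with a stiff adaptive solver
(`deSolve::lsoda`; the shipped rate constants span more than ten orders of
magnitude) at tolerances rtol = 1e-8, atol = 1e-9 µM. Negative excursions
are bounded by the tolerance scale and are clipped with a warning — never
silently. Halving the tolerances changes outputs by less than 1e-4
relative, and total fluorine is conserved to ~1e-13 relative in practice.

`steadyState()` relaxes the system by long integration over expanding
horizons and then polishes by a Newton iteration that solves the stacked
least-squares system $[J; C]\,\delta = [-f; 0]$, where $C$ are the
network's conservation vectors. This keeps conserved totals exact and
handles the structural singularity of the Jacobian along them. At the
depleted-ATP asymptote the model relaxes to a steady cycle through the
salvage triangle — reverse uracil phosphoribosyltransferase, the
hypothetical 5'-nucleotidase and uridine hydrolase — with persistent 5-FU,
FUDR and ADP, while FdTMP and fluorinated DNA survive only as inert
accumulator pools.

# Metabolic control analysis

Elasticities are computed by analytic differentiation of the three rate-law
kernels (finite differences agree to 1e-4; entries with zero rate or zero
concentration are reported as `NA`, never NaN). Control coefficients use
the structural matrix method: with $M = N\,\partial v/\partial x$ over the
kinetically active species, the response to a unit relative activity change
of enzyme $k$ (scaling $V_f$ and $V_r$ jointly) solves
$M\,\delta x = -N_k v_k$ subject to the *local* conserved quantities — the
left null vectors of $M$ — staying fixed.

This generalizes classical link-matrix reduction: at the depleted reference
state whole branches of the network are switched off, which creates
conserved quantities (e.g. the salvage-triangle total) that are not left
null vectors of the stoichiometry matrix alone. Detecting them on $M$
(after column equilibration, to which null spaces are invariant) makes the
summation theorems hold to ~1e-11 in practice: every defined
flux-control-coefficient row sums to 1 and every defined
concentration-control row to 0. We preferred this to the alternative of
re-solving perturbed steady states and differencing, which cannot reach
1e-6 summation accuracy reliably; the perturbation route is retained in the
test suite as an independent cross-check on a pathway with a textbook
closed form.

Species that influence no rate at the reference state (pure sinks whose
content is historical) have genuinely undefined control coefficients and
are reported as `NA`; the same applies to flux rows of reactions carrying
no flux. The elasticity extremes of the full model at its reference state
are huge (≫1e10) because some ping-pong denominators nearly vanish in the
depleted state; they are reported as computed, sign and cause/effect being
the meaningful content.

# Parameter estimation

The objective is weighted least squares over the NMR observable groups:
per-series weight $1/\mathrm{sd}(\text{observed})^2$ ("scaled standard
deviation" weighting; the original description names but does not define
the scaling — inverse variance is our documented reading). The sd is
floored at 1e-6 of the series scale so that conserved, constant series
(total fluorine) cannot dominate through numerical wiggle. A failed
simulation yields +Inf with a logged cause so the search continues.

`hookeJeeves()` is a classical pattern search: exploratory coordinate moves
with pattern extrapolation, step shrink factor ρ = 0.2, termination at step
< 1e-5 or 50 exploratory cycles — the published settings, which are also
the `fitProtocol()` defaults. `multistartFit()` runs the staged protocol:
log₁₀-space search (values span ~28 decades) within ±3 decades of the
start values, log-uniform random starts, one pre-minimization stage
(threshold 0.15), then consecutive restarts from the previous result until
the objective improves by less than 1e-6. The five most accurate attempts
are retained and summarized per parameter as bfv/avg/stds and
devStds = |bfv−avg|/stds (0 when the spread is 0). Everything is
reproducible bit-for-bit from the seed.

Recovering the published parameter values themselves is *not* a goal: the
original time courses exist only as figures. The estimation surface is
validated on synthetic data instead — grid-scan and quadratic/Rosenbrock
oracles for the optimizer, exact noiseless recovery, and
predicted-vs-observed R² ≥ 0.99 on a converged fit of the full model to 5%
noise data (the original analysis reports R² = 0.999 on its own data).

# Dose–survival and NMR helpers

Survival is $100/(1+(d/EC_{50})^{h})$ percent — 100% at zero dose,
50% at the EC50, decreasing for $h > 0$ (the printed formula's exponent
sign is typeset ambiguously; this convention matches the reported positive
Hill exponent and the described curve). `fitDoseResponse()` estimates
(log EC50, h) by Levenberg–Marquardt in log-dose space, which makes the
fit equivariant under dose-unit changes; standard errors come from the fit
Jacobian and the 95% band from the delta method. Flat or increasing data
fail identifiability explicitly. `t2FromLinewidth()` implements the
Lorentzian relation $T_2 = 1/(\pi\,\Delta\nu_{1/2})$: the ~17 Hz broad
signal of 5-FU in short unstructured RNA corresponds to $T_2 \approx 20$
ms.

# Synthetic data: what it emulates and what it does not

The generators emulate the study design — hourly ¹⁹F observations of six
NMR-indistinguishable groups over 1–17 h normalized to 1 mM total fluorine
(the t = 0 point is excluded, as in the experiment), a ³¹P relative ATP
curve, and dose–survival plates with five replicates. Default noise is 5%
relative Gaussian per point, our estimate of the integration error of a
1-h, 488-scan spectrum; dose–survival recovery experiments use 10%. All
generators are pure functions of configuration and seed.

They do **not** emulate spectral acquisition (lineshapes, overlap,
baseline), slow drifts, or model misspecification: passing recovery tests
shows the pipeline is correct and identifiable under the stated design, not
that the biological model is true.

## Problem sizes used in the shipped checks

The automated checks use deliberately compact designs: 100 seeded
dose–survival repeats of 40 points each; a 4-species, 6-parameter reduced
chain for exact-recovery tests; 2-parameter fits of the full model for the
fit-quality regression; and a single cached full-model steady state shared
by the control-analysis checks.

# Known limitations

* The initial state and the forced ATP curve are documented stand-ins for
  unavailable fitted values; trajectory *shapes* therefore match the study
  qualitatively, not point-wise.
* MCA at the depleted steady state is degenerate by nature; coefficients
  for empty pools and idle reactions are undefined and reported as `NA`.
* SBML export targets Level 3 core with the kinetic laws as MathML and the
  registry metadata (sharing, fixing, observables) in a package namespace;
  it round-trips exactly within the package but has not been validated
  against an external schema validator.
* The Hooke–Jeeves protocol inherits the published settings; it is a local
  search and relies on the multi-start layer for global behavior.

# A short tour

```{r tour, eval = FALSE}
net <- buildNetwork()
traj <- simulateNetwork(net, times = seq(0, 17, 0.5))
plotObservables(traj)

ss <- steadyState(net)
res <- mca(net, ss)
mcaExtremes(res)

tab <- generateDoseSurvival(seed = 1)
fitDoseResponse(tab$dose, tab$survival)
```
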