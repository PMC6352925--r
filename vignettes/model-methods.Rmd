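---
title: "The glycodyn model: dynamics of tumor-cell glycolysis and intermediate buffering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The glycodyn model: dynamics of tumor-cell glycolysis and intermediate buffering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Tumor cells show persistently high glucose uptake and lactate production
even with ample oxygen (the Warburg effect), and — more remarkably — can
transiently take up glucose an order of magnitude faster than that when
glucose is restored after a period of depletion. glycodyn implements a
coarse-grained kinetic model of this behaviour for Ehrlich ascites tumor
cells (EATC) and uses it to ask what the fast, dynamically regulated
uptake is *for*: the model's answer is that fructose 1,6-bisphosphate
(FBP) and the other phosphorylated glycolytic intermediates (PGI) act as
an energy and carbon buffer that carries the cell through the periodic
oxygen and glucose shortages caused by fluctuating tumor blood flow
(cycling hypoxia).

## The cell model

Glycolysis is lumped into two sections around the FBP pool.

**Head section** (glucose transport, hexokinase, phosphoglucose
isomerase, phosphofructokinase): consumes 1 glucose + 2 ATP per 6-carbon
unit and produces FBP,

$$ J_{head} = F_{active}\; V_{max,head}\;
   \frac{[glc]}{K_{m,glc}+[glc]}\;\frac{[ATP]}{K_{m,ATP}+[ATP]} $$

with $K_{m,glc} = 51\ \mu M$, the affinity that makes tumor cells
efficient glucose scavengers even below 100 µM glucose. The
two-substrate interaction is multiplicative by default
(`head_form = 1`); a ternary-complex denominator (`head_form = 2`) is
available, and at the calibrated operating points the two differ by less
than the calibration uncertainty, which is why we kept the simpler form.

**Delayed feedback**: the head section is slowly inactivated by the PGI
pool (a stand-in for the G6P/FBP feedback on hexokinase, with its >10 s
half-time) and slowly reactivated when PGI falls:

$$ \frac{dF_{active}}{dt} = -k_{inact}\,[PGI]\,F_{active}
   + k_{react}\,(1-F_{active}), \qquad [PGI] = r_{PGI}\,[FBP]. $$

Both boundary derivatives point inward, so $F_{active}$ stays in [0, 1]
without clamping. The fixed point
$F^\ast = k_{react}/(k_{react}+k_{inact}[PGI])$ reproduces the observed
regimes: fully disinhibited (100%) after starvation, ~7–11% at steady
11 mM glucose, intermediate (~16–23%) in tissue.

**Tail section** (aldolase through pyruvate kinase): per 3-carbon unit
consumes ½ FBP, 1 NAD⁺, 2 ADP, 1 P\(_i\) and yields 1 pyruvate, 1 NADH,
2 ATP. The rate is saturable in FBP, NAD⁺, ADP and P\(_i\) and inhibited
by NADH (`ki_nadh_tail`). The NADH brake is the mechanism behind the
pyruvate-protection experiment: with 5 mM external pyruvate, lactate
dehydrogenase (LDH) drains NADH so the tail never stalls, ATP never
collapses, and the adenine pool is spared. The reported
pyruvate-kinase activation by micromolar FBP is folded into
`km_fbp_tail` rather than modelled as a separate factor; the lumped Km
absorbs it and the calibration cannot distinguish the two.

**Lactate dehydrogenase**: a reversible two-substrate law in the
Lambeth–Kushmerick style with the reverse Vmax fixed by the Haldane
relationship, so the net flux vanishes exactly at
$[lac][NAD]/([pyr][NADH]) = K_{eq}$. Before glucose addition the cells
respire on abundant lactate through the reverse flux.

**Oxidative phosphorylation**: one saturable ATP-synthesis law in ADP,
P\(_i\) and O2, with small-constant gates on NADH and pyruvate so the
rate vanishes when mitochondrial substrates are truly absent while
remaining ADP/P\(_i\)/O2-limited under all study conditions. O2
consumption is coupled as $J_{O_2} = J_{ATP}/(2\,P/O)$ with $P/O = 2.5$
per O atom. Mitochondria draw pyruvate and NADH in 1:1 pairs (lactate
equivalents) at 3 O2 per pair, which makes full glucose oxidation
6 O2/glucose and lactate respiration 3 O2/lactate exactly.

**ATP demand and the adenine pool**: hydrolysis for maintenance and
growth is linear in the fall of the ATP+ADP pool,
$J_{hyd} = \max(0,\ hyd_{max} - s\,(A_0 - A))$, reproducing the ~70%
demand reduction in the first minute after a large glucose addition.
The pool itself degrades (to AMP, inosine, …, not tracked) first-order
in ADP above a threshold, and resynthesizes slowly
($k_{resyn}\approx 3\times10^{-4}\,s^{-1}$, a 0.5–1 h recovery). The
resynthesis term is included — deviating from the simplest reading that
pool recovery can be ignored within an hour — because the one-hour
Warburg/Crabtree averages require hydrolysis to drift back toward its
original rate during the incubation; without it the late-hour demand,
and with it the lactate and O2 rates, are systematically too low.
Inside the mass balances the hydrolysis demand is additionally
multiplied by $[ATP]/(K_{m}^{hyd}+[ATP])$ with a small
$K_m^{hyd} = 100\ \mu M$; this leaves normal operation untouched and
makes the rate vanish smoothly if ATP is exhausted, which is what keeps
every state non-negative without solver-level clamping.

**Biomass sink**: a first-order drain on the PGI pool (`k_sink`)
represents storage of glucose carbon as glycogen, nucleosides and amino
acids. The measured carbon partition five minutes after a 776 µM
addition (18% PGI, 43% lactate, 34% "other") cannot be reproduced
without it — with the sink off, PGI + lactate + CO2 must account for
everything — so the packaged EATC parameter set enables it, while the
bare parameter default is 0 and the partition report labels "other" as
an explicit residual rather than a mechanism.

**Phosphate bookkeeping**: every ADP→ATP phosphorylation consumes one
free P\(_i\) and every ATP→ADP step releases one (sugar-bound phosphate
is excluded from the free pool):
$dP_i/dt = J_{hyd} + 2J_{head} - 2J_{tail} - J_{ox} + J_{pool\,loss} -
J_{resyn}$. This is the only bookkeeping that leaves P\(_i\) stationary
at the glycolytic steady state.

## Parameters and provenance

Only a handful of the model's constants are pinned directly by published
numbers: $K_{m,glc} = 51\ \mu M$, the PGI:FBP ratio
$r_{PGI} = 1.24$ (≥5000 µM FBP carrying an extra ≥1200 µM 6C as other
PGI), the tissue flow waveforms (offset 4.4/amplitude 4.4 and offset
2.2/amplitude 3.5 ml·l⁻¹·s⁻¹), the 40 µm and 630 µm diffusion
geometries, and the 100 µM/s hydrolysis cap of the low-sensitivity
tissue scenario. Every other kinetic constant in
`inst/extdata/params/eatc_default.yml` was calibrated, once, against the
battery of quantitative EATC observations that the model is meant to
reproduce (initial uptake 295 µM/s and lactate 157 µM/s at 5 s after
776 µM glucose; >90% uptake reduction in 90 s; 30% ATP decline; ~70%
hydrolysis decline; 18/43/34 carbon partition; 52.5 µM/s lactate and
19.8 µM/s O2 over the aerobic hour; +61% lactate under anoxia; 44%
respiration reduction after glucose; ~700 µM FBP in 10 s from 77 µM
glucose; 7–11% steady head activity) using weighted least squares with
Nelder–Mead refinement. The calibrated set is frozen in the package; the
`calibration` module exists so users can re-fit any subset against their
own time courses.

Two deliberately simple choices to be aware of: the aerated suspension
holds dissolved O2 at 200 µM (air-saturated buffer at 37 °C) rather than
modelling gas exchange, and "glucose-depleted" initial states are
generated by integrating the model to its steady state on lactate
(fully disinhibited head, FBP near zero, intact adenine pool).

## Tissue extension

A Krogh cylinder: one well-mixed microvessel compartment (no axial
gradient) supplying `n_layers` concentric shells by radial Fickian
diffusion, with interface fluxes weighted by the annular areas.
Blood O2 is dissolved plus hemoglobin-bound via a Hill curve
(capacity 8000 µM, n = 2.7, C50 = 35 µM dissolved — rodent-standard
defaults, configurable). Arterial inflow (13 mM glucose — the elevated
blood glucose typical of the fed/hyperglycemic implanted-tumor
preparations, 90 µM dissolved O2, 1.5 mM lactate) and the vessel/shell
geometry belong to the transport-parameter set that is not printed in
full; they were calibrated once so that, at the stated constant flow of
4.4 ml·l⁻¹·s⁻¹, supply and demand sit in the regime the tissue results
describe — O2 delivery just above resting demand, near-complete glucose
extraction (tissue glucose a few hundred µM, the head section ~16%
active), and flow dips producing transient anoxia and glucose
depletion.

Each shell carries the full dynamic cell model for each cell type in
the mixture (types share the extracellular solutes of their shell;
volume shares are fixed). "Glycolytic capacity" scales the head and
tail Vmax jointly.

ATP synthesis is reported in three channels, defined exactly because
the published curves are defined only graphically:

* oxidative: $J_{ox}$;
* store-derived glycolytic: $2\max(0,\ J_{tail}-2J_{head})$ — the tail
  throughput not covered by concurrent head output, i.e. fed by net PGI
  depletion;
* throughput glycolytic: $2J_{tail}-2J_{head}$ minus the store term.

The three sum to total ATP synthesis identically. The
`uncouple_fbp_buffer` intervention discards the store-derived channel
from the ATP balance inside its time window (carbon flux continues),
reproducing the immediate ATP fall when the buffer is disabled during a
low-flow phase, and having no effect while the store is filling.

Numerics: method of lines; `deSolve::lsoda` (BDF when stiff) with
relative tolerance 1e-8 and absolute 1e-8 µM for cell-level runs, 1e-6
for the ~160-state tissue system; integration restarts at scenario
discontinuities (glucose addition, intervention windows). Rate laws
vanish smoothly at zero substrate, so negativity is prevented by the
dynamics; an assertion layer aborts any run in which a state
nevertheless undershoots beyond tolerance. Spin-up to the constant-flow
steady state precedes every cycling-flow simulation.

## Ascites extension

The same layered diffusion operator in planar geometry simulates
glucose entering cell-free ascites fluid (63 × 10 µm layers, initial
167 µM), and in radial geometry the steady state of a 25 vol%
cell suspension over 630 µm. Cells in the fluid run the full dynamic
model, so distant, glucose-starved layers show the disinhibited head
section. The simulation resolves the classical paradox that the
*sampled-average* glucose concentration of ascites fluid is many times
what most suspended cells actually see: the package reports the
volume-weighted mean alongside the profile for exactly this comparison.
The peritoneal boundary is a fixed concentration (a flux condition
would need a measured permeability that is not available); the fluid
diffusion coefficients default to free-solution values.

## Calibration and uncertainty module

`generate_synthetic_dataset()` simulates scenarios at known parameters
and adds multiplicative Gaussian noise at the classical sampling
instants — it stands in for the historical measurements, which are not
shipped. `fit_parameters()` minimizes weighted least squares (weights
1/scale² per observable so µM contents and µM/s rates are comparable)
with bounded L-BFGS-B on log-parameters and deterministic 8-point
multistart; flat objective directions are reported as structurally
non-identifiable, never silently returned. `uncertainty_ensemble()`
propagates either a Laplace (linearized-covariance) ensemble or a
residual-bootstrap refit ensemble to predictive bands.

## What the synthetic-data tests do and do not show

The parameter-recovery tests demonstrate that the estimation machinery
is correct (noiseless recovery to 1%, honest flagging of flat
directions) under the model's own error structure — independent
multiplicative Gaussian noise. Real kinetic measurements have
correlated errors, sampling-time jitter and systematic biases that the
generator does not emulate, so passing recovery tests validates the
software, not the identifiability of every parameter from any given
real data set.

## Problem sizes and defaults used in the shipped checks

The packaged checks run the suspension scenarios at full length (300 s
transients, 1 h steady-effect incubations) and the tissue scenarios
with a 2500 s constant-flow spin-up followed by 20 flow cycles (2000 s)
on 8 shells, averaging cycles 6–20; these sizes were chosen as the
smallest at which the cycle averages and hour averages are stable to
well under the tolerances being tested. The grid-refinement and
conservation checks use shortened windows of the same configurations,
and the capacity-ordering property (glucose uptake non-decreasing in
glycolytic capacity) is asserted at a frozen glucose-poor tissue state:
the ordering is a monotonicity property of the rate laws, so the frozen
environment tests the same fact as a full capacity sweep at a fraction
of the cost.

## Known limitations

* No reverse (gluconeogenic) glycolytic flux; the model cannot
  quantitate reverse fluxes.
* No explicit AMP/IMP/adenosine kinetics: pool loss is a one-way,
  slowly reversible leak, and free-energy (ΔG) accounting is out of
  scope.
* Single-vessel tissue abstraction: no vascular network, no flow
  regulation feedback, no reperfusion ROS.
* The enzyme-level identity of the delayed feedback is deliberately
  unresolved; `k_inact`/`k_react` describe its kinetics, not its
  mechanism.
* Cells do not move; the ascites geometry is static.
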