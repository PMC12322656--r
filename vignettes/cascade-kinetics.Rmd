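---
title: "Modelling the UMP-to-pseudouridine-5'-phosphate cascade: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the UMP-to-pseudouridine-5'-phosphate cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psicascade)
```

# The system

Pseudouridine 5'-phosphate (ΨMP) can be produced from UMP in one pot by two
enzymes: a nucleotide nucleosidase (PpnN or its R341A-Y347A double variant,
RY) cleaves UMP into uracil and D-ribose 5-phosphate, and the C-glycosidase
YeiN condenses those two back into the C-riboside ΨMP. The condensation is
strongly exergonic, so the overall rearrangement runs essentially to
completion. The catch is kinetic: Rib5P is a potent competitive inhibitor of
the nucleosidase (Km/Ki ≈ 11–13), so the cascade only runs at full speed if
YeiN removes Rib5P faster than it is released. This package models exactly
that interplay.

# Rate laws and their assumptions

**Nucleosidase.** `rate_inhibited_mm()` implements

$$v = \frac{V_{max}\,[\mathrm{UMP}]}{K_m\left(1 + [\mathrm{Rib5P}]/K_i\right) + [\mathrm{UMP}]},
\qquad V_{max} = k_{cat}\,[E],$$

purely competitive inhibition: the inhibitor raises the apparent $K_m$ by
$(1 + I/K_i)$ and leaves $k_{cat}$ untouched. Uncompetitive and mixed
alternatives are deliberately out of scope — the inhibition pattern of this
enzyme pair is competitive, and the estimation machinery fits only with or
without the competitive term. `[E]` is the molar *subunit* concentration
(`subunit_molarity()`, mass concentration over subunit molar mass); the
tetramer-versus-monomer difference between wild type and RY is ignored
because all kinetics are per subunit.

**C-glycosidase.** No full kinetic characterisation of the condensation
direction is available; the only anchor is one operating point, 7.0 U/mg at
15 mM of each substrate. `yein_params()` therefore uses an independent
two-substrate saturation law
$v = V_{max} \frac{A}{K_{m,A}+A}\frac{B}{K_{m,B}+B}$ with *assumed* Km
values of 1 mM for each substrate, and calibrates $k_{cat}$ so the law
reproduces the anchor exactly whatever Km pair is chosen (a property the
tests assert). The reverse (hydrolysis) reaction is omitted: the
condensation equilibrium lies far on the product side, and the model is
meant for the production regime. Consequences to keep in mind: simulated
cascades converge to 100% ΨMP at long times, and the shape (not the
endpoint) of the early Rib5P transient depends on the assumed Km values.

**What is not modelled.** Temperature, pH and Mn²⁺ are not state variables;
all constants refer to the 40 °C / pH 7.5 operating point at which they
were measured. Enzyme inactivation is not modelled (both enzymes are stable
over the relevant reaction times).

# Units

Concentrations are mM, time is minutes, rates mM/min. $k_{cat}$ is carried
in s⁻¹, as customarily reported, and converted (×60) only inside
`vmax_from_kcat()`. Specific activities use the standard unit
1 U = 1 µmol/min, so U/mg × subunit mass (g/mol) / 60000 gives the observed
per-subunit turnover in s⁻¹; `specific_activity_to_kcat()` additionally
corrects to saturation with $(K_m + S)/S$ and round-trips exactly with its
inverse.

# Simulation

`simulate_hydrolysis()` integrates $dS/dt = -v(S, S_0 - S)$;
`simulate_cascade()` integrates the four-species network with
$d[\mathrm{UMP}]/dt = -v_1$,
$d[\mathrm{Rib5P}]/dt = d[\mathrm{Ura}]/dt = v_1 - v_2$,
$d[\Psi\mathrm{MP}]/dt = v_2$. Both use `deSolve::lsoda` — the late,
inhibition-dominated phase is mildly stiff — at relative tolerance 1e-8 and
absolute tolerance 1e-10 mM. States are clipped at zero before rate
evaluation; no event handling is needed at these tolerances. Two mass
balances (`mass_balance_residuals()`) hold to better than 1e-8 × UMP₀ at
every output point.

The inhibited single-substrate ODE has a closed-form implicit solution,

$$t(S) = \frac{K_m\,(1 + S_0/K_i)\,\ln(S_0/S) + (1 - K_m/K_i)(S_0 - S)}{V_{max}},$$

which the test suite uses as an independent oracle (inverted by bisection):
over 100 random parameter sets the solver agrees with it to ≤1e-6 relative
error on 20-point grids.

`enzyme_ratio_sweep()` reproduces the kinetic-pull experiment: a fixed
total protein loading is split between the two enzymes at a series of
YeiN:PpnN mass ratios. In the simulated defaults (1.5 g/L total, 100 mM
UMP, 30 min evaluation) conversion plateaus for ratios ≥ 1 — the 1:1 and
2:1 splits land within 5% of each other — and collapses once YeiN is
strongly sub-stoichiometric, because Rib5P accumulates to many multiples of
Ki. At very large ratios conversion falls again as the nucleosidase itself
becomes limiting; the plateau is a ridge, not a half-line.

# Estimation

All fitters use unweighted least squares on rates (the convention of the
initial-rate regression tools this field uses; relative weighting would be
a one-line change) with parameters on the log scale to enforce positivity,
via `minpack.lm::nlsLM`. Starting values: $V_{max,0} = 1.2\times$ the
largest observed rate; $K_{m,0}$ = the substrate concentration whose rate
is closest to $V_{max,0}/2$; $K_{i,0} = K_{m,0}/10$. These are robust on
hyperbolic data. Standard errors come from the Jacobian (delta method back
from the log scale); `bootstrap_fit()` adds percentile intervals from
resampling points with replacement. Non-convergence is reported through the
`converged` flag of the fit object, never silently clamped; degenerate
designs (fewer than four distinct substrate concentrations) are rejected
up front.

`fit_ki_from_progress_curve()` holds $k_{cat}$ and $K_m$ at their
initial-rate values and minimises the squared deviation between observed
and simulated UMP(t) over $\log K_i$ with golden-section search across
$K_i \in [10^{-4}, 10^{5}]$ mM. Curves without an inhibition signal drive
the estimate to the upper end; anything above $1000 \times K_m$ is flagged
"no inhibition detectable" rather than reported as a real constant. Curves
covering less than 50% conversion only trigger a warning — the parameter is
then weakly identified but the fit is still defined.

`initial_rate_from_timecourse()` implements the below-20%-conversion rule:
a linear fit over the prefix of points with conversion under 20% (at least
three points). Note its built-in bias: under strong product inhibition
($K_i \ll 0.2\,S_0$) the rate has already dropped within that window, so
the rule underestimates the true initial rate. That is a property of the
rule itself, which is why the kinetic constants here come from dedicated
initial-rate assays at varied substrate, not from slopes of full progress
curves.

## A deliberate discrepancy: per-level apparent Km

Independent per-level Michaelis-Menten fits (`fit_apparent_km()`) of data
generated from a purely competitive model must show constant apparent
$k_{cat}$ and $K_{m,app}(I)/K_{m,app}(0) = 1 + I/K_i$ — at 10 mM Rib5P
that is 101-fold for the wild type ($K_i$ = 0.1 mM) and 9.3-fold for RY
($K_i$ = 1.2 mM). The empirical per-level fold-changes reported for the
real enzymes (≈40-fold and 6.7-fold) are *not* consistent with those
globally fitted $K_i$ values under pure competitive kinetics. The package
reproduces the model's predictions and the fitting machinery; it does not
attempt to reconcile the empirical numbers, and the acceptance tests assert
the model-predicted fold-changes explicitly. Likely causes of the gap
include noise in per-level $K_m$ estimates (an apparent $K_m$ of 111 mM is
poorly determined from a grid topping out near 30 mM) — which is also why
the per-level route is not the estimator of choice for $K_i$.

## Rounding of derived ratios

Derived ratios are computed from the recovered constants and rounded only
for display. Exact recovery of the wild-type preset gives
$k_{cat}/K_m = 2.6/1.1 = 2.36$, which rounds to 2.4 at one decimal while
the conventionally quoted value is 2.3; both are the same underlying
quantity quoted at different precision. RY gives 0.86 → 0.9, and the
$K_m/K_i$ ratios give 11.0 and 12.9 → 13.

# Synthetic data

The generator (`gen_initial_rates()`, `gen_progress_curve()`,
`gen_cascade_curves()`) evaluates the rate laws and simulations at the
preset constants and perturbs the observations with per-point independent
multiplicative Gaussian noise truncated at zero. The default CV of 0.16
matches the replicate spread of the specific-activity assays this emulates
(±1.6 on 9.8 U/mg over six replicates); recovery studies use CV = 0.10.
Default substrate grids are six concentrations spanning each enzyme's Km —
0.5–30 mM for wild type, 2–80 mM for RY — with inhibitor levels {0, 2, 10}
mM; the concentration grids actually used in the assays are unpublished, so
these are declared stand-ins. Everything is deterministic under a fixed
seed, and generated CSVs round-trip byte-identically.

What the generator does *not* emulate: correlated errors within a titration
series, baseline drift, HPLC peak integration artefacts, or enzyme
inactivation. Passing the recovery tests therefore shows the estimators are
correct and reasonably noise-robust, not that real assays of this system
will reach the same precision.

# Process metrics

`conversion_yield()`, `productivity()`, `ton_mass_based()`, `e_factor()`
and `scaleup_volume()` are deliberately small, exact functions; the value
is in their unit discipline and consistency checks. Mass metrics use the
anhydrous free acid of ΨMP (324.18 g/mol) — this is the mass that makes the
published productivity pair (294 g/L/h ↔ 906 mM/h), TON (≈103 g/g at
950 mM and 3.0 g/L) and scale-up volume (3.1 L/kg at 1 M) internally
consistent — while the disodium salt (368.15 g/mol) applies to gravimetric
yields of the isolated solid. E-factor accounting defaults to
water-included, enzymes-excluded; both toggles are exposed because waste
inventories are rarely standardised. The worked preparative ledger (1.84 g
UMP disodium, 0.009 g MnCl₂, ~4.5 g water after accounting for solute
volume in the 5.0 mL batch, a trace of NaOH, 1.60 g product) gives
E ≈ 3.0, and the tests check the sensitivity of that number to the
accounting toggles rather than a single decimal.

`build_route_table()` checks each route record's internal consistency — the
molar/mass productivity pair must be linked by the product molar mass
(0.5% relative tolerance: tight enough to catch a 900-vs-906 mM/h
substitution, loose enough for values rounded to integers), and the TON
must follow from titer, molar mass and loading (2.5%). Inconsistencies are
flagged, never corrected: in the shipped table of four published routes,
the Rib/Ura route's TON of 146 g/g does not follow from its titer and
loading and is flagged as such.

# Problem sizes

The statistical checks are sized to be convincing yet quick: 100 random
parameter sets for the ODE-versus-closed-form oracle, 200 replicates for
the noisy-Ki recovery (median error ≤ 15% at CV = 0.10), and a 30-dataset ×
300-replicate slice of the bootstrap-coverage property in the routine suite
(a full 100 × 500 run gives 94% coverage for Km and 89% for kcat at
nominal 95%, consistent with binomial fluctuation).

# Known limitations

* The YeiN Km values are assumptions anchored by a single operating point;
  simulated Rib5P transients (and thus the exact position of the
  ratio-sweep plateau edge) inherit that uncertainty.
* The irreversible YeiN law cannot describe the approach to a true
  equilibrium; do not use it to study the hydrolysis direction.
* Constants apply at 40 °C / pH 7.5 only; no temperature or pH dependence
  is modelled.
* The E-factor is as good as its ledger; the default preparative ledger
  reconstructs the batch from its recipe, not from a measured waste
  inventory.
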