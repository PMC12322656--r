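# psicascade

Kinetic analysis and process evaluation of the two-enzyme, one-pot
rearrangement of uridine 5′-phosphate (UMP) into pseudouridine 5′-phosphate
(ΨMP) — a key precursor of the modified mRNA building block pseudouridine.

A nucleosidase (PpnN, EC 3.2.2.10, or its faster and less product-inhibited
R341A-Y347A variant "RY") hydrolyses UMP into uracil (Ura) and D-ribose
5-phosphate (Rib5P); the ΨMP C-glycosidase YeiN (EC 4.2.1.70), run in its
condensation direction, couples Rib5P and Ura into ΨMP. Rib5P is a strong
competitive inhibitor of the nucleosidase, so the cascade lives or dies by
the *kinetic pull* of the second enzyme removing the intermediate. The
package is for biocatalysis researchers who want to model, fit and compare
such cascades from tabular initial-rate and time-course data.

## The model

The nucleosidase follows Michaelis–Menten kinetics with competitive product
inhibition by Rib5P:

    v = Vmax [UMP] / ( Km (1 + [Rib5P]/Ki) + [UMP] ),    Vmax = kcat [E]

with `[E]` the molar subunit concentration of the enzyme. Single-enzyme
hydrolysis is the ODE `dS/dt = −v(S, S0−S)` under the mass balance
UMP → Ura + Rib5P. The one-pot cascade couples this to an irreversible
two-substrate saturation law for YeiN:

    d[UMP]/dt  = −v1        d[Rib5P]/dt = d[Ura]/dt = v1 − v2
    d[ΨMP]/dt  =  v2        v2 = Vmax2 · A/(KmA+A) · B/(KmB+B)

Fitted constants (shipped as presets): wild-type PpnN kcat 2.6 s⁻¹, Km
1.1 mM, Ki 0.1 mM; RY kcat 13.4 s⁻¹, Km 15.5 mM, Ki 1.2 mM; YeiN calibrated
to its 7.0 U/mg operating point. Process metrics (yield, space-time yield,
mass-based TON, E-factor, scale-up volume) evaluate the preparative route.

## Worked example

Generate a noiseless synthetic initial-rate grid for RY (6 UMP
concentrations × Rib5P at 0, 2, 10 mM), fit the inhibition law globally,
and simulate a 100 mM hydrolysis at 2.0 mg/mL enzyme:

```r
library(psicascade)

d   <- gen_initial_rates("RY", i_grid = c(0, 2, 10))
fit <- fit_competitive_inhibition(d, preset_enzyme("RY"))
fit
#> <competitive-inhibition fit (global)> on 18 points (converged)
#> <kinetic_params> kcat = 13.4 1/s, Km = 15.5 mM, Ki = 1.2 mM
#>  term estimate std.error
#>  Vmax    1.563         0
#>    Km   15.500         0
#>    Ki    1.200         0
#>  kcat   13.400         0
glance(fit)$km_over_ki   # 12.9 -> "Km/Ki = 13": strong product inhibition

curve <- simulate_hydrolysis(enzyme_spec("RY", 51440, mass_conc = 2.0),
                             preset_params("RY"), s0 = 100,
                             t_grid = seq(0, 120, 30))
curve
#>   time_min     UMP_mM   Ura_mM Rib5P_mM PsiMP_mM
#>          0 100.000000  0.00000  0.00000        0
#>         30  24.524779 75.47522 75.47522        0
#>         60  10.535248 89.46475 89.46475        0
#>         90   4.883079 95.11692 95.11692        0
#>        120   2.328119 97.67188 97.67188        0
```

The exact recovery of the generating constants (zero residual) is the
self-consistency check every fitter passes; the 97.7% conversion at 120 min
shows RY clearing the ≥92% benchmark despite Km/Ki ≈ 13. Process metrics of
the preparative run (5 mmol UMP → 1.60 g isolated ΨMP disodium salt at
950 mM titer, 3.0 g/L total enzyme):

```r
out <- reaction_outcome(substrate_in = 5,
                        product_out = mmol_from_mass(1.60, molar_mass("PsiMP_disodium")),
                        titer = 950, duration = 1, volume = 0.005,
                        enzyme_load = 3.0)
conversion_yield(out)                 # 87 (%)
ton_mass_based(out)                   # 102.7 g product / g enzyme
scaleup_volume(1000, titer = 1000)    # 3.08 L of reaction per kg product
```

`autoplot()` methods exist for progress curves, initial-rate fits and
enzyme-ratio sweeps; `tidy()`/`glance()` give broom-style summaries of every
fit.

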