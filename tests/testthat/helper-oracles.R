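# Independent analytic oracles the ODE and fitting paths are checked
# against. The inhibited hydrolysis dS/dt = -Vmax S / (Km (1 + (S0-S)/Ki) + S)
# has the implicit closed-form solution
#   t(S) = [Km (1 + S0/Ki) ln(S0/S) + (1 - Km/Ki)(S0 - S)] / Vmax
# (Ki = Inf gives the classic integrated Michaelis-Menten form).

implicit_time <- function(s, s0, vmax, km, ki = Inf) {
  if (is.infinite(ki)) {
    (km * log(s0 / s) + (s0 - s)) / vmax
  } else {
    (km * (1 + s0 / ki) * log(s0 / s) + (1 - km / ki) * (s0 - s)) / vmax
  }
}

# Invert the implicit solution by bisection: substrate remaining at time t.
oracle_substrate_at <- function(t, s0, vmax, km, ki = Inf) {
  vapply(t, function(tt) {
    if (tt <= 0) return(s0)
    f <- function(s) implicit_time(s, s0, vmax, km, ki) - tt
    stats::uniroot(f, c(s0 * 1e-12, s0 * (1 - 1e-12)), tol = 1e-13)$root
  }, numeric(1))
}

# Enzyme spec whose loading gives an exact Vmax (mM/min) for a given kcat.
enzyme_for_vmax <- function(vmax, kcat, molar_mass = 50000) {
  e_mM <- vmax / (60 * kcat)
  enzyme_spec("synthetic", molar_mass, mass_conc = e_mM * molar_mass / 1000)
}

ry_enzyme <- function(mass_conc = 2.0) enzyme_spec("RY", 51440, mass_conc)
wt_enzyme <- function(mass_conc = 2.0) enzyme_spec("WT_PPNN", 51794, mass_conc)
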