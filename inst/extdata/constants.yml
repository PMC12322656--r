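# Versioned constants table: enzyme subunit masses, extinction coefficients,
# molar masses and kinetic parameter presets used throughout the package.
version: 1
enzymes:
  WT_PPNN:
    subunit_molar_mass: 51794    # g/mol, per subunit
    assay_mass_conc: 0.4         # g/L used in the standard initial-rate assay
  RY:
    subunit_molar_mass: 51440
    assay_mass_conc: 0.1
  YEIN:
    subunit_molar_mass: 32909
    assay_mass_conc: 0.025
extinction_mM:                   # small-molecule coefficients, 1/(mM cm)
  Ura:   {wavelength: 258, epsilon: 8.3}
  UMP:   {wavelength: 262, epsilon: 10.0}
  PsiMP: {wavelength: 262, epsilon: 7.5}
protein_extinction_M:            # protein A280 coefficients, 1/(M cm)
  YeiN:    {wavelength: 280, epsilon: 10095, molar_mass: 32909}
  # The printed PpnN/RY values are identical to YeiN's and inconsistent with
  # the 51.4-51.8 kDa subunit masses; stored as printed but flagged suspect.
  PpnN_RY: {wavelength: 280, epsilon: 10095, molar_mass: 32909, suspect: true}
molar_mass:                      # g/mol
  PsiMP_disodium: 368.15
  PsiMP_free_acid: 324.18        # C9H13N2O9P, anhydrous
  UMP_disodium: 368.15
  UMP_free_acid: 324.18
  Psi: 244.20                    # C9H12N2O6
  Ura: 112.09
  Rib5P: 230.11
kinetics:
  WT_PPNN: {kcat: 2.6,  km: 1.1,  ki: 0.1}   # s^-1, mM, mM
  RY:      {kcat: 13.4, km: 15.5, ki: 1.2}
  YEIN_DEFAULT:
    km_rib5p: 1.0     # mM, assumed default (not measured); see vignette
    km_ura: 1.0       # mM, assumed default
    calibration: {specific_activity: 7.0, rib5p: 15.0, ura: 15.0}  # U/mg at mM,mM
solubility_limit_UMP: 1500       # mM, warn above this
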