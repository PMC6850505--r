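# Default physicochemical parameter set for liquid-water radiolysis.
# Units are stated in the key names; values are converted to internal
# units (nm, ps, eV) once, when the registry is built.
species:
  - {name: "H3O+",  D_m2_per_s: 9.0e-9, charge:  1}
  - {name: "H",     D_m2_per_s: 7.0e-9, charge:  0}
  - {name: "OH-",   D_m2_per_s: 5.0e-9, charge: -1}
  - {name: "e_aq",  D_m2_per_s: 4.9e-9, charge: -1}
  - {name: "H2",    D_m2_per_s: 5.0e-9, charge:  0}
  - {name: "OH",    D_m2_per_s: 2.8e-9, charge:  0}
  - {name: "H2O2",  D_m2_per_s: 1.4e-9, charge:  0}

# Bimolecular channels; water is implicit (bulk solvent) where it appears as
# a reactant or product in the balanced equation.
reactions:
  - {reactants: ["e_aq", "e_aq"], products: ["H2", "OH-", "OH-"], k_dm3_per_mol_s: 5.00e+9}
  - {reactants: ["e_aq", "OH"],   products: ["OH-"],              k_dm3_per_mol_s: 2.95e+10}
  - {reactants: ["e_aq", "H"],    products: ["OH-", "H2"],        k_dm3_per_mol_s: 2.65e+10}
  - {reactants: ["e_aq", "H3O+"], products: ["H"],                k_dm3_per_mol_s: 2.11e+10}
  - {reactants: ["e_aq", "H2O2"], products: ["OH-", "OH"],        k_dm3_per_mol_s: 1.41e+10}
  - {reactants: ["OH", "OH"],     products: ["H2O2"],             k_dm3_per_mol_s: 4.40e+9}
  - {reactants: ["OH", "H"],      products: [],                   k_dm3_per_mol_s: 1.44e+10}
  - {reactants: ["H", "H"],       products: ["H2"],               k_dm3_per_mol_s: 1.20e+10}
  - {reactants: ["H3O+", "OH-"],  products: [],                   k_dm3_per_mol_s: 1.43e+11}

# Branching of activated water. Per parent state the fractions sum to 100.
# Relaxation returns the molecule to the ground state (no species produced,
# the excess energy is released locally).
dissociation:
  - {parent: "ionized",          mode: "dissociative_decay", products: ["H3O+", "OH"],         fraction_percent: 100}
  - {parent: "A1B1",             mode: "dissociative_decay", products: ["OH", "H"],            fraction_percent: 65}
  - {parent: "A1B1",             mode: "relaxation",         products: [],                     fraction_percent: 35}
  - {parent: "B1A1",             mode: "auto_ionization",    products: ["H3O+", "OH", "e_aq"], fraction_percent: 55}
  - {parent: "B1A1",             mode: "dissociative_decay", products: ["OH", "OH", "H2"],     fraction_percent: 15}
  - {parent: "B1A1",             mode: "relaxation",         products: [],                     fraction_percent: 30}
  - {parent: "rydberg_diffuse",  mode: "auto_ionization",    products: ["H3O+", "OH", "e_aq"], fraction_percent: 50}
  - {parent: "rydberg_diffuse",  mode: "relaxation",         products: [],                     fraction_percent: 50}
  - {parent: "dissoc_attachment", mode: "dissociative_decay", products: ["OH", "OH-", "H2"],   fraction_percent: 100}

constants:
  avogadro: 6.02214076e+23
  water_density_g_cm3: 1.0
  water_molar_mass_g_mol: 18.0153
  sub_excitation_threshold_eV: 8.22
  dt_min_ps: 1.0
  chem_t_start_ps: 1.0
  chem_t_end_ps: 1.0e+6
  tracking_cuts_eV:
    electron: 7.4
    proton: 100.0
    hydrogen: 100.0
    He0: 1000.0
    "He+": 1000.0
    "He++": 1000.0
    generic_ion_per_u: 5.0e+5
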