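# Toy cross-section table set for liquid water.
#
# Deliberately simple totals (constants and gentle power laws, interpolated
# log-log) with fixed-loss / uniform-secondary samplers. The set is
# self-consistent and exercises every transport path (all five electron
# processes, proton/hydrogen charge exchange, helium charge states) but is
# NOT a high-fidelity physics model; swap in externally produced tables of
# the same schema for quantitative physics work.
processes:
  # ---- electrons --------------------------------------------------------
  - particle: electron
    process: elastic
    angle: isotropic
    E_eV:      [7.4, 1.0e+6]
    sigma_nm2: [2.0e-4, 2.0e-4]
  - particle: electron
    process: ionization
    binding_eV: 13.0
    secondary_fraction_max: 0.5
    E_eV:      [13.0, 100.0, 1.0e+3, 1.0e+4, 1.0e+6]
    sigma_nm2: [1.0e-4, 3.0e-4, 2.0e-4, 1.0e-4, 3.0e-5]
  - particle: electron
    process: excitation
    state: A1B1
    loss_eV: 8.22
    E_eV:      [8.22, 100.0, 1.0e+6]
    sigma_nm2: [6.0e-5, 8.0e-5, 1.0e-5]
  - particle: electron
    process: excitation
    state: B1A1
    loss_eV: 10.0
    E_eV:      [10.0, 100.0, 1.0e+6]
    sigma_nm2: [5.0e-5, 7.0e-5, 8.0e-6]
  - particle: electron
    process: excitation
    state: rydberg_diffuse
    loss_eV: 11.5
    E_eV:      [11.5, 100.0, 1.0e+6]
    sigma_nm2: [3.0e-5, 4.0e-5, 5.0e-6]
  - particle: electron
    process: vibrational
    loss_eV: 0.4
    E_eV:      [2.0, 100.0]
    sigma_nm2: [2.0e-4, 1.0e-4]
  - particle: electron
    process: attachment
    E_eV:      [4.0, 13.0]
    sigma_nm2: [2.0e-5, 2.0e-5]
  # ---- protons ----------------------------------------------------------
  - particle: proton
    process: elastic
    E_eV:      [100.0, 1.0e+8]
    sigma_nm2: [1.0e-4, 1.0e-4]
  - particle: proton
    process: excitation
    state: B1A1
    loss_eV: 10.0
    E_eV:      [500.0, 1.0e+8]
    sigma_nm2: [2.0e-4, 2.0e-5]
  - particle: proton
    process: ionization
    binding_eV: 13.0
    secondary_fraction_max: 0.5
    secondary_max_eV: 200.0
    E_eV:      [100.0, 1.0e+4, 1.0e+6, 2.0e+7, 1.0e+8]
    sigma_nm2: [5.0e-3, 3.0e-3, 1.0e-3, 5.0e-4, 2.0e-4]
  - particle: proton
    process: charge_decrease
    E_eV:      [100.0, 1.0e+4]
    sigma_nm2: [1.0e-4, 1.0e-4]
  # ---- neutral hydrogen --------------------------------------------------
  - particle: hydrogen
    process: elastic
    E_eV:      [100.0, 1.0e+8]
    sigma_nm2: [1.0e-4, 1.0e-4]
  - particle: hydrogen
    process: ionization
    binding_eV: 13.0
    secondary_fraction_max: 0.5
    secondary_max_eV: 200.0
    E_eV:      [100.0, 1.0e+8]
    sigma_nm2: [1.0e-3, 2.0e-4]
  - particle: hydrogen
    process: charge_increase
    loss_eV: 13.6
    E_eV:      [100.0, 1.0e+8]
    sigma_nm2: [2.0e-4, 2.0e-4]
  # ---- helium charge states ---------------------------------------------
  - particle: He0
    process: ionization
    binding_eV: 13.0
    secondary_fraction_max: 0.5
    secondary_max_eV: 500.0
    E_eV:      [1.0e+3, 1.0e+8]
    sigma_nm2: [2.0e-3, 4.0e-4]
  - particle: He0
    process: charge_increase
    loss_eV: 24.6
    E_eV:      [1.0e+3, 1.0e+8]
    sigma_nm2: [3.0e-4, 3.0e-4]
  - particle: "He+"
    process: ionization
    binding_eV: 13.0
    secondary_fraction_max: 0.5
    secondary_max_eV: 500.0
    E_eV:      [1.0e+3, 1.0e+8]
    sigma_nm2: [3.0e-3, 6.0e-4]
  - particle: "He+"
    process: charge_increase
    loss_eV: 54.4
    E_eV:      [1.0e+3, 1.0e+8]
    sigma_nm2: [2.0e-4, 2.0e-4]
  - particle: "He+"
    process: charge_decrease
    E_eV:      [1.0e+3, 1.0e+6]
    sigma_nm2: [2.0e-4, 2.0e-4]
  - particle: "He++"
    process: ionization
    binding_eV: 13.0
    secondary_fraction_max: 0.5
    secondary_max_eV: 500.0
    E_eV:      [1.0e+3, 1.0e+8]
    sigma_nm2: [4.0e-3, 8.0e-4]
  - particle: "He++"
    process: charge_decrease
    E_eV:      [1.0e+3, 1.0e+6]
    sigma_nm2: [2.0e-4, 2.0e-4]
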