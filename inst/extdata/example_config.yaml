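# Example run configuration: calibration standards and validation thresholds.
seed: 1
depletion_time: 12
standards:
  - name: "EmGFP (in-house)"
    molar_mass_g_per_mol: 26900
    stock_conc: 12600        # mg/L, determined at A487
    purity: 0.78
    excitation_nm: 487
    emission_nm: 509
    solvent: "PBS"
    ph: 7.0
  - name: "GFP (commercial)"
    molar_mass_g_per_mol: 26900
    stock_conc: 1000
    purity: 0.70
    excitation_nm: 475
    emission_nm: 509
    solvent: "PBS"
    ph: 7.0
  - name: "Na-F*"
    # disodium-salt molar mass, consistent with 1 uM = 0.376 mg/L
    molar_mass_g_per_mol: 376.27
    stock_conc: 0.752        # mg/L (2.00 uM stock)
    purity: 1.0
    excitation_nm: 485
    emission_nm: 514
    solvent: "100 mM NaOH"
    ph: 13.0
thresholds:
  min_r_squared: 0.99
  max_recovery_dev_pct: 15
  max_intraday_rsd_pct: 10
  max_interday_rsd_pct: 20
paths:
  output_dir: "results"
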