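# Example batch configuration for run_yield_table() / run_repair_table().
# The proton parameters below are the shipped calibration of the
# zero-modifier baseline (see the vignette); refit with damage_model()
# for full reproducibility.
qualities:
  - name: proton62MeV
    let_keV_um: 1.051
    cluster_rate_rho: 616.15
    multiplicity_nu: 0.80
    p_strand_break: 0.199
    nseg: 25
    scavenger_preset: proton62MeV
conditions:
  - {dmso_M: 0.0, o2_percent: 21}
  - {dmso_M: 0.1, o2_percent: 21}
  - {dmso_M: 0.5, o2_percent: 21}
  - {dmso_M: 1.0, o2_percent: 21}
pathways: [SP_BER, LP_BER, NER_SP_BER, NER_LP_BER]
n_clusters: 100000
dose: 1
seed: 1
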