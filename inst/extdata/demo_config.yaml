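# Demo configuration: simulate a two-study, five-population count matrix
# and run every pipeline stage on it.
seed: 1
simulation:
  n_genes: 2000
  n_signature: 150
  baseline_mean: 100
  dispersion: 0.1
  signature_log2fc: 2
  batch_log2shift_sd: 0.25
stages:
  vst_dispersion: 0.1
  presence_cutoff: 10
  linkage: average
  cascade:
    fc_cut: 1.2
    p_cut: 0.001
    expr_cut: 5
    cons_cut: 0.5
  volcano:
    p_cut: 1.0e-16
    lfc_cut: 2
qpcr:
  n_replicates: 3
  target_delta_ct:
    control: 5.0
    treated: 1.4
  noise_sd: 0.3
  treated: treated
  control: control
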