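# Example simulation scenario for the CLI `simulate` verb and
# read_scenario_config(). Any omitted block falls back to the defaults
# shown in ?read_scenario_config.
scheme:
  n_t1_complex: 64
  dt1: 0.0002        # s; indirect spectral width 5000 Hz, t1_max 12.8 ms
  n_t2: 200
  dt2: 0.0005        # s
  scans_per_fid: 2
  recycle_delay: 0.1 # s
  acq_window: 0.1    # s
resonances:
  n_resonances: 50
  seed: 1
  ranges:
    r2_ind: [50, 50] # 1/s; uniform indirect decay, IDP-like
water_fraction: 0.02 # 2% exchangeable protons (deuterated HyperW buffer)
kex_threshold: 2     # 1/s; slower-exchanging residues stay invisible
decay:
  epsilon: 300       # enhancement at t1 = 0
  rate: 450          # 1/s on the t1 axis (= 0.45 per ms)
noise_sigma: 0.004   # relative to the strongest time-domain point
seed: 1
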