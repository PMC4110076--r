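neuron_exc:
  C_m: 1.0
  g_Na: 35.0
  g_K: 9.0
  g_L: 0.1
  E_Na: 55.0
  E_K: -90.0
  E_L: -65.0
neuron_inh:
  C_m: 0.5
  g_Na: 35.0
  g_K: 9.0
  g_L: 0.1
  E_Na: 55.0
  E_K: -90.0
  E_L: -65.0
syn_ampa:
  tau_d: 2.0
  tau_r: 0.5
  g_max: 0.0135
  E_syn: 0.0
syn_gaba:
  tau_d: 4.5
  tau_r: 0.5
  g_max: 0.055
  E_syn: -80.0
syn_ext:
  tau_d: 2.0
  tau_r: 0.5
  g_max: 0.006
  E_syn: 0.0
drive:
  nu0: 1500.0
  sigma: 400.0
  tau_ou: 16.0
  clip_at_zero: yes
  shared_ou: yes
  inh_drive_gain: 1.2
network:
  'N': 2000.0
  frac_exc: 0.8
  mean_degree: 100.0
  rewiring_p: 0.3
coupling:
  frac_source_exc: 0.9
  frac_target: 0.25
  tau_inter: 0.0
  delay_mode: gamma
  unidirectional: no
sim:
  dt: 0.05
  duration: 2.0
  warmup: 0.2
  fs_record: 1000.0
  v_thresh: 0.0
  refractory: 2.0
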