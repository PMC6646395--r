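# Adaptive high-frequency DBS on the default network: the configuration
# used by the README's worked example.
network:
  N: 200
  seed: 1
controller:
  mode: aDBS
  K: 1.2
  Th_on: 0.016
  Th_off: 0.008
  T_ramp: 1000
pulse:
  F_hz: 130
  PW: 0.2
  GW: 0
simulation:
  t_total: 18000
  t_stim_on: 5000
  t_skip: 3000
  ic_seed: 7
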