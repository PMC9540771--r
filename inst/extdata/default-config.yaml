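# Baseline parameterisation of the seasonal obligate-killer model.
# All quantities in season-time units.
model:
  s_hat: 1.0e+08   # emerging host cohort size (hosts)
  t_l: 1.0         # host emergence period length (time)
  mu: 0.5          # background host death rate (1/time)
  tau: 1.5         # delay infection -> parasite-induced death (time)
  alpha: 1.0e-08   # transmission rate (1/(parasite * time))
  beta: 200        # progeny released at host death (parasites)
  delta: 2.0       # free-living parasite decay rate (1/time)
  T: 3.0           # season length (time)
  v_init: 1.0      # start-of-season free parasite density
tradeoff:
  kind: none       # none | linear_positive | linear_negative
  a: 99
  b: 0.5
ibm:
  n_hosts: 10000
  seed: 1
  n_replicates: 50
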