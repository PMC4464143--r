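n: 10000
seed: 1
p_exposure: 0.9
T_mem: 1
r: 1.0
rho: 1.0
dose:
  family: delta
  value: 1.0
threshold:
  family: delta
  value: 0.5
contagious_state: PEA
dosing_mode: all
init_infected_fraction: 0.5
t_max: 300
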