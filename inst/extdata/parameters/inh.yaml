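# Inhibitory (fast-spiking) GIF parameters, mouse barrel cortex.
# Units: C pF, g_L nS, voltages mV, times ms, lambda_0 kHz.
cell_class: inh
C: 46.1
g_L: 6.6
E_L: -71.2
t_ref: 4.0
V_reset: -48.4
lambda_0: 10.0
delta_V: 0.6
V_T_star: -41.2
eta:
  - amplitude: 31.8
    time_constant: 11.5
  - amplitude: 1.6
    time_constant: 500.1
gamma:
  - amplitude: 5.6
    time_constant: 11.5
  - amplitude: 0.6
    time_constant: 473.7
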