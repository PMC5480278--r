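# Layer-5A excitatory (pyramidal) GIF parameters, mouse barrel cortex.
# Units: C pF, g_L nS, voltages mV, times ms, lambda_0 kHz.
cell_class: exc
C: 83.1
g_L: 3.7
E_L: -67.0
t_ref: 4.0
V_reset: -36.7
lambda_0: 10.0
delta_V: 1.4
V_T_star: -39.6
eta:                       # spike-triggered adaptation current (pA)
  - amplitude: 56.7
    time_constant: 57.8
  - amplitude: -6.9
    time_constant: 218.2
gamma:                     # spike-triggered threshold movement (mV)
  - amplitude: 11.7
    time_constant: 53.8
  - amplitude: 1.8
    time_constant: 640.0
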