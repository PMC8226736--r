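# Calibrated vehicle-specific parameters shipped as package defaults.
# Units: cm/min for rates and velocities; eta_dep dimensionless.
model_a:
  u: 43            # wind velocity, cm/min
model_b:
  u: 0.68          # wind velocity, cm/min
  pbs:
    eta_dep: 0.03
    kevap_veh: 0.0055
  ethanol:
    eta_dep: 0.05
    kevap_veh: 0.014
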