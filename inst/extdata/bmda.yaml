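# Physicochemical property record for benzenemethanol,alpha,alpha-
# dimethyl-acetate (BMDA), the acetylated derivative of the urinary
# cumene metabolite 2-phenyl-2-propanol. Temperature-dependent constants
# are tagged with the sampling temperature they were established at.
name: BMDA
molecular_formula: C11H14O2
by_temperature:
  - temperature_c: 60
    log_kow: 2.88
    henry_constant: 5.25e-4   # atm m^3/mol
  - temperature_c: 10
    log_kow: 3.41
    henry_constant: 5.58e-5   # atm m^3/mol
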