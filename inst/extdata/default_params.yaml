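# Default reaction and population parameters (literature-derived rates for a
# LuxI/LuxR quorum-sensing implementation in E. coli).
kappa: 35.0        # Hold rate constant, h^-1
rho: 14.0          # Reset rate constant, h^-1
"n": 4.0          # Hill coefficient
K: 8.0e+7          # half-activation density, mL^-1
P: 1.5e+8          # total population density, mL^-1
sigma_A: 1.0       # detection rate per analyte unit, h^-1
sigma_err: 0.0     # erroneous detection rate, h^-1
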