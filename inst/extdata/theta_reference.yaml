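CL_HEALTHY: 2540.0
CL_MILD: 1550.0
CL_MODERATE: 1326.0
VC: 51400.0
Q_HEALTHY: 33678.0
Q_MILD: 38800.0
Q_MODERATE: 63554.0
VP: 410000.0
RA: 0.653
GAM1: 4.57
KAMAX: 0.86
BMI_VP: 0.058
F1: 1.0
BMI_REF: 27.0
SIGMA: 0.1788
OMEGA_CL: 0.4347
OMEGA_VC: 0.2123
OMEGA_Q: 0.3646
OMEGA_VP: 0.2705
OMEGA_RA: 0.3255
OMEGA_GAM1: 0.3807
OMEGA_KAMAX: 0.3178
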