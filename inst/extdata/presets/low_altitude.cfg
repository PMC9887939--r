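# reference parameter set (low-altitude shrub phenotype); P in mm/y
P: 1000
E1: 16
E2: 5
K1: 0.7
K2: 0.35
M1: 7.05
M2: 7.05
N: 15
Lam1: 0.06
Lam2: 0.16
Gam1: 15
Gam2: 5
R1: 0.1
R2: 0.1
Th1: 3.125
Th2: 3.125
DW: 0.5
SG1: 0.5
SD1: 0.5
SD2: 0.01
Wstar1: 0.5
Wstar2: 2.0
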