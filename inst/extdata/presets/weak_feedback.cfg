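# non-pattern-forming control: root augmentation too weak for patterning
P: 1400
E1: 2
E2: 5
K1: 1.75
K2: 0.35
M1: 9.05
M2: 9.05
N: 15
Lam1: 0.08
Lam2: 0.08
Gam1: 5
Gam2: 5
R1: 0.1
R2: 0.1
Th1: 3.125
Th2: 3.125
DW: 1
SG1: 0.01
SD1: 0.1
SD2: 0.01
Wstar1: 0.5
Wstar2: 0.5
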