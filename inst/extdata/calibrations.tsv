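# Built-in divergence-time calibration bounds (kyr) for main-trunk Y
# haplogroups. Configuration data at literature scale for generating dating
# inputs; supply your own calibrations for real analyses.
haplogroup	lower	upper
A	200	300
B	80	110
C	45	70
D	45	70
E	50	80
F	40	65
G	15	30
H	30	50
I	25	45
J	25	45
K	35	55
N	15	35
O	25	40
Q	15	35
R	20	40
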