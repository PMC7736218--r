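label	x	y
Fp1	-0.16	0.85
Fpz	0	0.85
Fp2	0.16	0.85
AF7	-0.64	0.65
AF3	-0.32	0.65
AFz	0	0.65
AF4	0.32	0.65
AF8	0.64	0.65
F7	-0.64	0.45
F5	-0.48	0.45
F3	-0.32	0.45
F1	-0.16	0.45
Fz	0	0.45
F2	0.16	0.45
F4	0.32	0.45
F6	0.48	0.45
F8	0.64	0.45
FT7	-0.64	0.22
FC5	-0.48	0.22
FC3	-0.32	0.22
FC1	-0.16	0.22
FCz	0	0.22
FC2	0.16	0.22
FC4	0.32	0.22
FC6	0.48	0.22
FT8	0.64	0.22
T7	-0.64	0
C5	-0.48	0
C3	-0.32	0
C1	-0.16	0
Cz	0	0
C2	0.16	0
C4	0.32	0
C6	0.48	0
T8	0.64	0
TP9	-0.8	-0.22
TP7	-0.64	-0.22
CP5	-0.48	-0.22
CP3	-0.32	-0.22
CP1	-0.16	-0.22
CPz	0	-0.22
CP2	0.16	-0.22
CP4	0.32	-0.22
CP6	0.48	-0.22
TP8	0.64	-0.22
TP10	0.8	-0.22
P7	-0.64	-0.45
P5	-0.48	-0.45
P3	-0.32	-0.45
P1	-0.16	-0.45
Pz	0	-0.45
P2	0.16	-0.45
P4	0.32	-0.45
P6	0.48	-0.45
P8	0.64	-0.45
PO7	-0.64	-0.65
PO3	-0.32	-0.65
POz	0	-0.65
PO4	0.32	-0.65
PO8	0.64	-0.65
O1	-0.16	-0.85
Oz	0	-0.85
Iz	0	-0.95
O2	0.16	-0.85
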