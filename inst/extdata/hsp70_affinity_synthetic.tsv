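residue	value
A	0.2
R	0.6
N	-0.4
D	-1.2
C	0.1
Q	-0.3
E	-1.2
G	-0.2
H	0.0
I	1.0
L	1.4
K	0.3
M	0.8
F	1.0
P	-0.8
S	-0.2
T	-0.1
W	0.9
Y	0.6
V	0.9
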