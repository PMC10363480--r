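row	column	core	mito	chloro	note
A	a	B2I	FULL	NONE	results_enumeration
A	b	MII	PARTIAL	NONE	results_enumeration
A	c	R2G	NONE	NONE	inferred_none
A	d	DS4	NONE	NONE	inferred_none
A	e	DDM	NONE	NONE	inferred_none
A	f	B1E	NONE	NONE	inferred_none
A	g	CP3	NONE	NONE	inferred_none
A	h	S1D	NONE	NONE	inferred_none
A	i	E1S	NONE	NONE	inferred_none
A	j	LCA	NONE	NONE	inferred_none
A	k	SIM	NONE	NONE	inferred_none
A	l	B15	NONE	NONE	inferred_none
A	m	EHF	NONE	NONE	inferred_none
B	a	B2I	FULL	NONE	results_enumeration
B	b	MII	FULL	NONE	results_enumeration
B	c	R2G	PARTIAL	NONE	results_enumeration
B	d	DS4	NONE	NONE	inferred_none
B	e	DDM	NONE	NONE	inferred_none
B	f	B1E	NONE	NONE	inferred_none
B	g	CP3	PARTIAL	NONE	results_enumeration
B	h	S1D	NONE	NONE	inferred_none
B	i	E1S	NONE	NONE	inferred_none
B	j	LCA	NONE	NONE	inferred_none
B	k	SIM	NONE	NONE	inferred_none
B	l	B15	NONE	NONE	inferred_none
B	m	EHF	NONE	NONE	inferred_none
B	q	MH	PARTIAL	NONE	control
C	a	B2I	FULL	NONE	inferred_consistent
C	b	MII	FULL	NONE	inferred_low_confidence
C	c	R2G	PARTIAL	NONE	results_enumeration
C	d	DS4	NONE	NONE	inferred_none
C	e	DDM	NONE	NONE	inferred_none
C	f	B1E	NONE	NONE	inferred_none
C	g	CP3	NONE	NONE	inferred_none
C	h	S1D	NONE	NONE	inferred_none
C	i	E1S	NONE	NONE	inferred_none
C	j	LCA	NONE	NONE	inferred_none
C	k	SIM	NONE	NONE	inferred_none
C	l	B15	NONE	NONE	inferred_none
C	m	EHF	NONE	NONE	inferred_none
C	q	MH	PARTIAL	NONE	control_low_confidence
D	a	B2I	FULL	NONE	inferred_consistent
D	b	MII	FULL	NONE	inferred_consistent
D	c	R2G	FULL	NONE	results_enumeration
D	d	DS4	NONE	NONE	inferred_none
D	e	DDM	NONE	NONE	inferred_none
D	f	B1E	NONE	NONE	inferred_none
D	g	CP3	FULL	NONE	results_enumeration
D	h	S1D	NONE	NONE	inferred_none
D	i	E1S	PARTIAL	NONE	results_enumeration
D	j	LCA	NONE	NONE	inferred_none
D	k	SIM	NONE	NONE	inferred_none
D	l	B15	NONE	NONE	inferred_none
D	m	EHF	NONE	PARTIAL	results_enumeration
D	q	MH	PARTIAL	NONE	control
E	a	B2I	FULL	NONE	inferred_consistent
E	b	MII	PARTIAL	NONE	inferred_consistent
E	c	R2G	PARTIAL	NONE	inferred_low_confidence
E	d	DS4	NONE	NONE	inferred_none
E	e	DDM	NONE	NONE	inferred_none
E	f	B1E	NONE	NONE	inferred_none
E	g	CP3	NONE	NONE	inferred_none
E	h	S1D	NONE	FULL	results_enumeration
E	i	E1S	NONE	NONE	inferred_none
E	j	LCA	NONE	PARTIAL	results_enumeration
E	k	SIM	NONE	NONE	inferred_none
E	l	B15	NONE	PARTIAL	results_enumeration
E	m	EHF	NONE	PARTIAL	results_enumeration
F	a	B2I	FULL	NONE	inferred_consistent
F	b	MII	PARTIAL	NONE	inferred_consistent
F	c	R2G	PARTIAL	NONE	inferred_low_confidence
F	d	DS4	NONE	NONE	inferred_none
F	e	DDM	NONE	NONE	inferred_none
F	f	B1E	NONE	NONE	inferred_none
F	g	CP3	NONE	PARTIAL	results_enumeration
F	h	S1D	NONE	PARTIAL	results_enumeration
F	i	E1S	NONE	NONE	inferred_none
F	j	LCA	NONE	PARTIAL	results_enumeration
F	k	SIM	NONE	NONE	inferred_none
F	l	B15	NONE	PARTIAL	results_enumeration
F	m	EHF	NONE	FULL	results_enumeration
F	q	MH	NONE	PARTIAL	control
G	a	B2I	PARTIAL	NONE	results_enumeration
G	b	MII	PARTIAL	NONE	inferred_low_confidence
G	c	R2G	PARTIAL	NONE	results_enumeration
G	d	DS4	NONE	NONE	inferred_none
G	e	DDM	PARTIAL	NONE	results_enumeration
G	f	B1E	NONE	NONE	inferred_none
G	g	CP3	NONE	NONE	inferred_none
G	h	S1D	PARTIAL	NONE	results_enumeration
G	i	E1S	NONE	NONE	inferred_none
G	j	LCA	NONE	NONE	inferred_none
G	k	SIM	NONE	PARTIAL	results_enumeration
G	l	B15	NONE	NONE	inferred_none
G	m	EHF	NONE	NONE	inferred_none
H	a	B2I	PARTIAL	NONE	results_enumeration
H	b	MII	PARTIAL	NONE	inferred_low_confidence
H	c	R2G	FULL	NONE	results_enumeration
H	d	DS4	NONE	NONE	inferred_none
H	e	DDM	PARTIAL	NONE	results_enumeration
H	f	B1E	PARTIAL	NONE	results_enumeration
H	g	CP3	NONE	PARTIAL	results_enumeration
H	h	S1D	PARTIAL	NONE	results_enumeration
H	i	E1S	NONE	PARTIAL	results_enumeration
H	j	LCA	NONE	NONE	inferred_none
H	k	SIM	NONE	FULL	results_enumeration
H	l	B15	NONE	PARTIAL	results_enumeration
H	m	EHF	NONE	PARTIAL	results_enumeration
H	p	CH	NONE	NONE	control
I	a	B2I	PARTIAL	NONE	results_enumeration
I	b	MII	PARTIAL	NONE	results_enumeration
I	c	R2G	PARTIAL	NONE	inferred_low_confidence
I	d	DS4	NONE	NONE	inferred_none
I	e	DDM	NONE	NONE	inferred_none
I	f	B1E	PARTIAL	PARTIAL	results_enumeration
I	g	CP3	NONE	PARTIAL	results_enumeration
I	h	S1D	PARTIAL	PARTIAL	results_enumeration
I	i	E1S	NONE	PARTIAL	results_enumeration
I	j	LCA	NONE	PARTIAL	results_enumeration
I	k	SIM	NONE	PARTIAL	results_enumeration
I	l	B15	NONE	PARTIAL	results_enumeration
I	m	EHF	NONE	PARTIAL	results_enumeration
I	p	CH	NONE	NONE	control_low_confidence
J	a	B2I	PARTIAL	PARTIAL	results_enumeration
J	b	MII	PARTIAL	PARTIAL	results_enumeration
J	c	R2G	PARTIAL	NONE	inferred_low_confidence
J	d	DS4	NONE	NONE	inferred_none
J	e	DDM	NONE	NONE	inferred_none
J	f	B1E	PARTIAL	PARTIAL	results_enumeration
J	g	CP3	NONE	NONE	inferred_none
J	h	S1D	PARTIAL	PARTIAL	results_enumeration
J	i	E1S	NONE	PARTIAL	results_enumeration
J	j	LCA	NONE	NONE	inferred_none
J	k	SIM	NONE	PARTIAL	results_enumeration
J	l	B15	NONE	PARTIAL	results_enumeration
J	m	EHF	NONE	PARTIAL	results_enumeration
J	q	MH	NONE	NONE	control
K	a	B2I	NONE	PARTIAL	results_enumeration
K	b	MII	NONE	PARTIAL	results_enumeration
K	c	R2G	PARTIAL	NONE	inferred_consistent
K	d	DS4	NONE	NONE	inferred_none
K	e	DDM	NONE	PARTIAL	results_enumeration
K	f	B1E	NONE	PARTIAL	results_enumeration
K	g	CP3	NONE	NONE	inferred_none
K	h	S1D	NONE	PARTIAL	results_enumeration
K	i	E1S	NONE	PARTIAL	results_enumeration
K	j	LCA	NONE	PARTIAL	results_enumeration
K	k	SIM	NONE	PARTIAL	results_enumeration
K	l	B15	NONE	PARTIAL	results_enumeration
K	m	EHF	NONE	PARTIAL	results_enumeration
K	n	RP1	NONE	NONE	control
K	o	RP2	NONE	NONE	control
K	p	CH	NONE	NONE	control_low_confidence
K	r	-	NONE	PARTIAL	control
K	s	AA	NONE	PARTIAL	control
L	a	B2I	NONE	FULL	results_enumeration
L	b	MII	NONE	PARTIAL	results_enumeration
L	c	R2G	PARTIAL	PARTIAL	results_enumeration
L	d	DS4	NONE	NONE	inferred_none
L	e	DDM	NONE	PARTIAL	results_enumeration
L	f	B1E	NONE	FULL	results_enumeration
L	g	CP3	NONE	PARTIAL	results_enumeration
L	h	S1D	NONE	PARTIAL	results_enumeration
L	i	E1S	NONE	PARTIAL	results_enumeration
L	j	LCA	NONE	FULL	results_enumeration
L	k	SIM	NONE	PARTIAL	results_enumeration
L	l	B15	NONE	PARTIAL	results_enumeration
L	m	EHF	NONE	PARTIAL	results_enumeration
L	n	RP1	NONE	NONE	control
L	o	RP2	NONE	NONE	control
L	p	CH	NONE	FULL	control
L	q	MH	NONE	PARTIAL	control
L	r	-	NONE	PARTIAL	control
L	s	AA	NONE	PARTIAL	control
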