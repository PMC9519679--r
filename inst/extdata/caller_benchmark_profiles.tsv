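sv_type	caller	category	sensitivity_pct	precision_pct
DEL	Delly	A	58.1	97.8
DEL	Delly	B	76.2	99.4
DEL	Delly	C	72.5	99.3
DEL	Delly	D	72.4	100.0
DEL	Delly	E	75.0	100.0
DEL	Manta	A	79.7	100.0
DEL	Manta	B	81.1	99.8
DEL	Manta	C	79.9	99.6
DEL	Manta	D	79.7	99.4
DEL	Manta	E	81.0	100.0
DEL	Lumpy	A	60.0	78.1
DEL	Lumpy	B	70.5	86.5
DEL	Lumpy	C	66.8	85.6
DEL	Lumpy	D	62.5	79.0
DEL	Lumpy	E	64.3	80.6
DEL	GRIDSS	A	79.0	99.5
DEL	GRIDSS	B	80.7	99.9
DEL	GRIDSS	C	77.8	99.9
DEL	GRIDSS	D	78.1	100.0
DEL	GRIDSS	E	77.4	100.0
DEL	Pindel	A	87.4	99.9
DEL	Pindel	B	68.4	99.7
DEL	Pindel	C	83.6	99.4
DEL	Pindel	D	80.2	100.0
DEL	Pindel	E	67.9	100.0
DEL	NGSEP	A	84.1	87.3
DEL	NGSEP	B	83.1	83.4
DEL	NGSEP	C	83.5	82.2
DEL	NGSEP	D	87.5	89.8
DEL	NGSEP	E	78.6	75.0
INS	Delly	A	3.4	100.0
INS	Manta	A	88.4	99.8
INS	Manta	B	74.1	100.0
INS	Manta	C	72.1	100.0
INS	Manta	D	72.5	100.0
INS	Manta	E	75.0	100.0
INS	GRIDSS	A	45.5	100.0
INS	Pindel	A	6.6	93.0
INS	NGSEP	A	64.1	59.2
INS	NGSEP	B	26.8	29.6
INS	NGSEP	C	35.5	40.5
INS	NGSEP	D	30.5	32.1
INS	NGSEP	E	26.0	26.5
DUP	Delly	A	28.2	99.0
DUP	Delly	B	75.1	96.8
DUP	Delly	C	74.7	95.4
DUP	Delly	D	75.3	97.2
DUP	Delly	E	71.7	91.7
DUP	Manta	A	39.0	99.5
DUP	Manta	B	80.5	99.8
DUP	Manta	C	82.7	99.8
DUP	Manta	D	83.9	98.7
DUP	Manta	E	82.6	97.4
DUP	Lumpy	A	31.5	98.4
DUP	Lumpy	B	67.9	84.8
DUP	Lumpy	C	67.7	82.6
DUP	Lumpy	D	68.3	81.9
DUP	Lumpy	E	65.2	80.0
DUP	GRIDSS	A	39.4	99.8
DUP	GRIDSS	B	80.0	100.0
DUP	GRIDSS	C	80.0	100.0
DUP	GRIDSS	D	83.3	100.0
DUP	GRIDSS	E	79.4	100.0
DUP	Pindel	A	75.7	98.1
DUP	Pindel	B	57.8	99.0
DUP	Pindel	C	88.1	99.8
DUP	Pindel	D	83.9	99.4
DUP	Pindel	E	73.9	100.0
INV	Delly	A	49.7	70.4
INV	Delly	B	84.6	99.2
INV	Delly	C	85.5	99.4
INV	Delly	D	82.6	99.4
INV	Delly	E	78.2	98.6
INV	Manta	A	77.0	99.0
INV	Manta	B	87.0	99.9
INV	Manta	C	87.3	99.9
INV	Manta	D	90.0	100.0
INV	Manta	E	82.8	100.0
INV	Lumpy	A	66.1	88.5
INV	Lumpy	B	76.8	96.2
INV	Lumpy	C	75.3	97.4
INV	Lumpy	D	77.4	94.8
INV	Lumpy	E	74.7	98.5
INV	GRIDSS	A	76.9	99.1
INV	GRIDSS	B	86.9	99.8
INV	GRIDSS	C	85.2	99.9
INV	GRIDSS	D	87.9	100.0
INV	GRIDSS	E	82.8	100.0
INV	Pindel	A	83.5	99.2
INV	Pindel	B	90.7	99.9
INV	Pindel	C	90.2	99.9
INV	Pindel	D	89.0	100.0
INV	Pindel	E	77.0	100.0
INV	NGSEP	A	0.0	0.0
INV	NGSEP	B	75.7	87.9
INV	NGSEP	C	75.3	81.5
INV	NGSEP	D	80.0	85.4
INV	NGSEP	E	77.0	88.2
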