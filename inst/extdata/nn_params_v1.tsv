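# mirsite nearest-neighbor duplex parameter table
# version: mirsite-nn-1.0
# units: kcal/mol at 37C; stack keys are pair1/pair2 with pair x:y written xy,
# read 5'->3' on the microRNA strand (pair1 stacks on pair2).
term	key1	key2	value
stack	AU	AU	-0.93
stack	AU	UA	-1.1
stack	AU	GC	-2.08
stack	AU	CG	-2.24
stack	AU	GU	-0.94
stack	AU	UG	-0.5
stack	UA	AU	-1.33
stack	UA	UA	-0.93
stack	UA	GC	-2.11
stack	UA	CG	-2.35
stack	UA	GU	-0.95
stack	UA	UG	-0.42
stack	GC	AU	-2.35
stack	GC	UA	-2.24
stack	GC	GC	-3.26
stack	GC	CG	-3.42
stack	GC	GU	-1.47
stack	GC	UG	-1.01
stack	CG	AU	-2.11
stack	CG	UA	-2.08
stack	CG	GC	-2.36
stack	CG	CG	-3.26
stack	CG	GU	-1.06
stack	CG	UG	-0.94
stack	GU	AU	-1.06
stack	GU	UA	-1.01
stack	GU	GC	-1.47
stack	GU	CG	-1.54
stack	GU	GU	-0.66
stack	GU	UG	-0.45
stack	UG	AU	-0.6
stack	UG	UA	-0.42
stack	UG	GC	-0.95
stack	UG	CG	-1.06
stack	UG	GU	-0.43
stack	UG	UG	-0.19
bulge	1		3.8
bulge	2		2.8
bulge	3		3.2
bulge	4		3.6
bulge	5		4
bulge	6		4.4
bulge	7		4.6
bulge	8		4.7
bulge	9		4.8
bulge	10		4.9
bulge	11		5
bulge	12		5.1
bulge	13		5.2
bulge	14		5.3
bulge	15		5.4
interior	2		1.5
interior	3		1.8
interior	4		2
interior	5		2.2
interior	6		2.5
interior	7		2.7
interior	8		2.9
interior	9		3.1
interior	10		3.3
interior	11		3.5
interior	12		3.7
interior	13		3.9
interior	14		4.1
interior	15		4.3
interior	16		4.5
interior	17		4.7
interior	18		4.9
interior	19		5.1
interior	20		5.3
interior	21		5.5
interior	22		5.7
interior	23		5.9
interior	24		6.1
interior	25		6.3
interior	26		6.5
interior	27		6.7
interior	28		6.9
interior	29		7.1
interior	30		7.3
init			4.09
terminal			0.45
max_loop_side			15
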