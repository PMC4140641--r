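# RNA/RNA nearest-neighbor stack free energies, kcal/mol at 37 C
# Turner 2004 parameter set (Watson-Crick and GU wobble pairs).
# Row = 5' pair (top base, bottom base) of the stack step 5'-WX-3'/3'-ZY-5',
# i.e. row key = WZ; column = pair read 3'->5' on entry, column key = YX.
# Energy of the step is M[WZ, YX].
pair	CG	GC	GU	UG	AU	UA
CG	-2.40	-3.30	-2.10	-1.40	-2.10	-2.10
GC	-3.30	-3.40	-2.50	-1.50	-2.20	-2.40
GU	-2.10	-2.50	1.30	-0.50	-1.40	-1.30
UG	-1.40	-1.50	-0.50	0.30	-0.60	-1.00
AU	-2.10	-2.20	-1.40	-0.60	-1.10	-0.90
UA	-2.10	-2.40	-1.30	-1.00	-0.90	-1.30
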