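# Terminal charge patches (synthetic; same provenance and style as charges.tsv).
# action: set = replace the charge of an existing atom; add = atom introduced
# by the patch; del = atom removed by the patch.
# NTER converts the amide into a protonated amine (+1 net); CTER converts the
# carbonyl into a carboxylate (-1 net).
# Columns: patch, atom, action, charge.
patch	atom	action	charge
NTER	HN	del	0
NTER	N	set	-0.30
NTER	HT1	add	0.33
NTER	HT2	add	0.33
NTER	HT3	add	0.33
NTER	CA	set	0.21
NTER	HA	set	0.10
CTER	O	del	0
CTER	C	set	0.34
CTER	OT1	add	-0.67
CTER	OT2	add	-0.67
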