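# Chothia CDR boundaries (scheme residue numbers, inclusive; insertion codes
# inherit the membership of their base number). Editable data, not code.
# Columns: region, chain, start, end.
region	chain	start	end
CDRH1	heavy	26	32
CDRH2	heavy	52	56
CDRH3	heavy	95	102
CDRL1	light	24	34
CDRL2	light	50	56
CDRL3	light	89	97
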