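# Backbone atom names (everything else is side chain). Glycine's HA2 is
# deliberately absent so that glycine has a defined side-chain surface area.
N
CA
C
O
OXT
OT1
OT2
HN
H
HA
HA1
HT1
HT2
HT3
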