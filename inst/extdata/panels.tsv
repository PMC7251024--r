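panel	pattern
Na+/K+-ATPase	^Atp1
Nav	^Scn
Kv	^Kcn
KCa	^Kcnm|^Kcnn
Cav	^Cacn
Cl-	^Clcn
AMPA	^Gria
Delta	^Grid
Kainate	^Grik
NMDA	^Grin
GABA-A	^Gabr
nACh	^Chrn
5-HT	^Htr
mGlu	^Grm
mGABA	^Gabbr
mACh	^Chrm
DA	^Drd
2-AG	^Cnr
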