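>c6A_synthetic_ref synthetic stand-in for mature cytochrome c6A reference (canonical frame: diagnostic V at 52, 12-residue 2-Cys LIP at 39-50)
DCTSDDYGYKDISCMICHRRSIFARNGNFETMLSWLGEIMCPYDSAQCNIHVHMCEKIRP
HNWFTKISVMRYQLTTAGKMVVSECKQSIRMNWFSTIIRAAPTT
>c6_synthetic_ref synthetic stand-in for mature cytochrome c6 reference (diagnostic Q at 40, no LIP)
DCTSDDYGYKDISCMICHRRSIFARNGNFETMLSWLGEHQHMCEKIRPHNWFTKISVMRY
QLTTAGKMVVSECKQSIRMNWFSTIIRAAPTT
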