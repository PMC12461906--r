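; Toy Martini-3-style lipid templates (synthetic bead geometries, nm).
; Head bead first and at maximal z; tails extend toward -z.
[ POPC ]
bead NC3 0.000000 0.000000 0.000000
bead PO4 0.000000 0.000000 -0.300000
bead GL1 0.000000 0.000000 -0.550000
bead GL2 0.120000 0.000000 -0.550000
bead C1A 0.000000 0.000000 -0.850000
bead C2A 0.000000 0.000000 -1.150000
bead C3A 0.000000 0.000000 -1.450000
bead C1B 0.120000 0.000000 -0.850000
bead C2B 0.120000 0.000000 -1.150000
bead C3B 0.120000 0.000000 -1.450000

[ CDL ]
bead GL0 0.000000 0.000000 0.000000
bead PO1 -0.120000 0.000000 -0.250000
bead PO2 0.120000 0.000000 -0.250000
bead GL1 -0.120000 0.000000 -0.500000
bead GL2 0.120000 0.000000 -0.500000
bead C1A -0.120000 0.000000 -0.800000
bead C2A -0.120000 0.000000 -1.100000
bead C3A -0.120000 0.000000 -1.400000
bead C1B 0.120000 0.000000 -0.800000
bead C2B 0.120000 0.000000 -1.100000
bead C3B 0.120000 0.000000 -1.400000

[ CHOL ]
bead ROH 0.000000 0.000000 0.000000
bead R1 0.000000 0.000000 -0.300000
bead R2 0.000000 0.000000 -0.600000
bead C1 0.000000 0.000000 -0.900000

[ DLPC ]
bead NC3 0.000000 0.000000 0.000000
bead PO4 0.000000 0.000000 -0.300000
bead GL1 0.000000 0.000000 -0.550000
bead C1A 0.000000 0.000000 -0.850000
bead C2A 0.000000 0.000000 -1.100000
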