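# Reactive / unstable motifs excluded from fragment libraries.
# Format: name <whitespace> SMARTS. Edit freely; names appear in rejection
# reports. Aryl halides and aliphatic fluorides are deliberately NOT listed
# (fluorinated fragments are a first-class library class).
acyl_halide        [CX3](=[OX1])[F,Cl,Br,I]
aldehyde           [CX3H1](=O)[#6]
michael_acceptor   [CX3]=[CX3]-[CX3]=[OX1]
alkyl_halide       [CX4][Cl,Br,I]
anhydride          [CX3](=[OX1])[OX2][CX3](=[OX1])
isocyanate         [NX2]=[CX2]=[OX1]
isothiocyanate     [NX2]=[CX2]=[SX1]
epoxide            [OX2r3]1[#6r3][#6r3]1
aziridine          [NX3r3]1[#6r3][#6r3]1
peroxide           [OX2][OX2]
thioester          [SX2][CX3]=[OX1]
azide              N=[N+]=[N-]
thiol              [SX2H1]
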