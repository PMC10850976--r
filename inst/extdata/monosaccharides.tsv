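symbol	class	formula	residue_mass
HexNAc	monosaccharide	C8H13NO5	203.0793725
Hex	monosaccharide	C6H10O5	162.0528234
Fuc	monosaccharide	C6H10O4	146.0579088
NeuAc	monosaccharide	C11H17NO8	291.0954165
NeuGc	monosaccharide	C11H17NO9	307.0903311
Pent	monosaccharide	C5H8O4	132.0422587
HexA	monosaccharide	C6H8O6	176.0320880
Phospho	substituent	HPO3	79.9663305
Sulfate	substituent	SO3	79.9568146
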