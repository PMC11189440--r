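center_cm1,tol_cm1,assignment,sign
734,8,tryptophan ring breathing,negative
855,8,tryptophan/tyrosine ring breathing,negative
1233,8,amide III beta-sheet,negative
1316,8,amide III alpha-helix,negative
1559,8,tryptophan indole ring (amide II region),negative
1008,8,phenylalanine phenyl ring breathing,positive
1034,8,phenylalanine phenyl ring,positive
1181,8,tyrosine/phenylalanine CH bend,positive
1410,8,COO- symmetric stretch,positive
1449,8,CH2/CH3 deformation,positive
1603,8,phenyl ring C=C,positive
1735,8,lipid ester C=O stretch,positive
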