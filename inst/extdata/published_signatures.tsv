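signature_name	n_conserved48_members
Benita	3
Betts/Eustace	9
Buffa	13
Elvidge	14
Ghazoui	11
Halle	5
Hu	5
Ortiz-Barahoma	6
Ragnum	4
Seigneuric	10
Sorensen	18
Toustrup	8
Winter	10
Yang	1
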