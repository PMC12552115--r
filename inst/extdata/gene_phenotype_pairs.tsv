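# description=gene-phenotype pairs for the reference SLP table; direction says whether damaging rare variants associate with case or control status
gene	phenotype_name	direction
LDLR	hyperlipidaemia	case
ABCG5	hyperlipidaemia	case
NPC1L1	hyperlipidaemia	control
PCSK9	hyperlipidaemia	control
APOC3	hyperlipidaemia	control
ANGPTL3	hyperlipidaemia	control
DNMT3A	hypertension	case
FES	hypertension	case
ASXL1	hypertension	case
SMAD6	hypertension	case
NPR1	hypertension	case
GUCY1A1	hypertension	case
INPPL1	hypertension	control
DBH	hypertension	control
GCK	type_2_diabetes	case
HNF4A	type_2_diabetes	case
HNF1A	type_2_diabetes	case
GIGYF1	type_2_diabetes	case
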