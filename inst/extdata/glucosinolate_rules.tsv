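locus	symbol	layer	direction	phenotype	note
At4g03050	AOP2	T	up	alkenyl_higher
At4g03060	AOP3	T	up	hydroxyalkyl_higher	possible cross-hybridization with the AOP2 probe
At5g23010	MAM1	T	up	C4_higher
At2g43100	MAM-I	T	up	C4_higher
At2g43100	MAM-I	P	up	C4_higher
At5g14200	MAM-D	P	up	C4_higher
At1g31180	MAM-D	P	up	C4_higher
At1g54040	ESP	P	up	nitriles_hydrolysis
At1g54040	ESP	P	down	isothiocyanates_hydrolysis
At3g14210	ESM1	T	up	isothiocyanates_hydrolysis
At3g14210	ESM1	T	down	nitriles_hydrolysis
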