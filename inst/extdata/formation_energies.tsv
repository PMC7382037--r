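id	formula	charge	phase	dgf0_prime_kj_mol	dhf0_prime_kj_mol	source
h2	H2	0	gas	0	0	thauer1977
o2	O2	0	gas	0	0	thauer1977
h2o	H2O	0	liquid_water	-237.17	-285.83	thauer1977/nbs1982
hplus	H	1	aqueous	0	0	convention
co2	CO2	0	gas	-394.36	-393.51	thauer1977/nbs1982
hco3	CHO3	-1	aqueous	-586.85	-691.99	thauer1977/nbs1982
ch4	CH4	0	gas	-50.75	-74.81	thauer1977/nbs1982
formate	CHO2	-1	aqueous	-351.04	-425.55	thauer1977/nbs1982
acetate	C2H3O2	-1	aqueous	-369.41	-486.01	thauer1977/nbs1982
propionate	C3H5O2	-1	aqueous	-361.08		thauer1977
butyrate	C4H7O2	-1	aqueous	-352.63		thauer1977
isobutyrate	C4H7O2	-1	aqueous	-353.96		estimate_branched_isomer
isovalerate	C5H9O2	-1	aqueous	-347.10		estimate_branched_isomer
methylbutyrate2	C5H9O2	-1	aqueous	-352.20		estimate_branched_isomer
glucose	C6H12O6	0	aqueous	-917.22	-1263.78	thauer1977/nbs1982
nh4	H4N	1	aqueous	-79.37	-132.51	thauer1977/nbs1982
h2s	H2S	0	gas	-33.56	-20.63	thauer1977/nbs1982
ch3sh	CH4S	0	aqueous	-7.59		derived_gas_plus_henry
alanine	C3H7NO2	0	aqueous	-371.54		thauer1977
glycine	C2H5NO2	0	aqueous	-370.79		thauer1977
glutamate	C5H8NO4	-1	aqueous	-699.60		thauer1977
glutamine	C5H10N2O3	0	aqueous	-529.70		thauer1977
aspartate	C4H6NO4	-1	aqueous	-700.40		thauer1977
asparagine	C4H8N2O3	0	aqueous	-525.93	 	thauer1977
isoleucine	C6H13NO2	0	aqueous	-343.90		thauer1977
leucine	C6H13NO2	0	aqueous	-352.25		thauer1977
valine	C5H11NO2	0	aqueous	-356.93		thauer1977
lysine	C6H14N2O2	0	aqueous	-336.20		thauer1977
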