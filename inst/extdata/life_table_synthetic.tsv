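# SYNTHETIC life table: annual probability of death q by sex and age.
# Values are realistic for a contemporary high-income country's children
# (order 1e-4) but are constructed, not taken from an official life table.
sex	age_years	q
M	4	0.00013
M	5	0.000123
M	6	0.000117
M	7	0.00011
M	8	0.000103
M	9	9.67e-05
M	10	9e-05
M	11	0.000128
M	12	0.000166
M	13	0.000204
M	14	0.000242
M	15	0.00028
F	4	1e-04
F	5	9.5e-05
F	6	9e-05
F	7	8.5e-05
F	8	8e-05
F	9	7.5e-05
F	10	7e-05
F	11	8.8e-05
F	12	0.000106
F	13	0.000124
F	14	0.000142
F	15	0.00016
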