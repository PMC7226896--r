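fusion	five_gene	five_pos	three_gene	three_pos
PAX3-FOXO1	PAX3	7500	FOXO1	1500
PAX3-INO80D	PAX3	7500	INO80D	208500
PAX3-NCOA1_type1	PAX3	6500	NCOA1	112500
PAX3-NCOA1_type2	PAX3	7500	NCOA1	111500
PAX7-FOXO1	PAX7	2500	FOXO1	1500
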