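family_id	rep_id
fam01	rep_fam01
fam02	rep_fam02
fam03	rep_fam03
fam04	rep_fam04
fam05	rep_fam05
fam06	rep_fam06
fam07	rep_fam07
fam08	rep_fam08
fam09	rep_fam09
fam10	rep_fam10
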