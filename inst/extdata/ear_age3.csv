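sex,age_years,kcal
male,3,1171
female,3,1076
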