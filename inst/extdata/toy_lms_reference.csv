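sex,age_years,L,M,S
male,2,-1.35,16.6,0.078
male,3,-1.45,16.2,0.08
male,4,-1.55,15.9,0.083
male,5,-1.65,15.7,0.086
male,6,-1.75,15.6,0.09
male,7,-1.85,15.7,0.094
male,8,-1.9,15.9,0.098
female,2,-1.3,16.3,0.082
female,3,-1.4,16,0.085
female,4,-1.5,15.7,0.088
female,5,-1.6,15.5,0.092
female,6,-1.7,15.4,0.096
female,7,-1.8,15.5,0.1
female,8,-1.85,15.8,0.104
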