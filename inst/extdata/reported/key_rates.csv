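name,numerator,denominator
overall_discordance,378060,4722660
overall_missingness,1132220,5854880
missingness_white,752820,4250000
missingness_asian,65510,186180
missingness_nhpi,2640,6760
multiracial_both_sources,640,127160
hispanic_pattern_top10,38570,135810
intra_census_acs_vs_2020,13780,270230
intra_census_decennial,347540,4840000
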