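group,ehr_count,census_count
Hispanic,57840,135940
White,252360,57980
Black,35540,20620
AIAN,10020,19580
Asian,10750,16810
NHPI,10380,1780
Multiracial,1300,125500
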