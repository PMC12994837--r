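source_code,category
hispanic,Hispanic
hispanic or latino,Hispanic
latino,Hispanic
latina,Hispanic
latinx,Hispanic
mexican,Hispanic
puerto rican,Hispanic
cuban,Hispanic
other hispanic,Hispanic
non-hispanic,NotHispanic
not hispanic,NotHispanic
not hispanic or latino,NotHispanic
nonhispanic,NotHispanic
white,White
caucasian,White
european,White
w,White
black,Black
black or african american,Black
african american,Black
african-american,Black
b,Black
aian,AIAN
american indian,AIAN
alaska native,AIAN
american indian or alaska native,AIAN
native american,AIAN
asian,Asian
asian indian,Asian
chinese,Asian
filipino,Asian
japanese,Asian
korean,Asian
vietnamese,Asian
other asian,Asian
a,Asian
nhpi,NHPI
native hawaiian,NHPI
pacific islander,NHPI
native hawaiian or other pacific islander,NHPI
guamanian or chamorro,NHPI
samoan,NHPI
other pacific islander,NHPI
multiracial,Multiracial
two or more races,Multiracial
multiple races,Multiracial
biracial,Multiracial
unknown,Unreported
unreported,Unreported
declined,Unreported
declined to answer,Unreported
patient declined,Unreported
refused,Unreported
other,Unreported
other race,Unreported
unavailable,Unreported
not reported,Unreported
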