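source_code,system,icd10_code
250.00,ICD9,E11.9
250.02,ICD9,E11.65
250.60,ICD9,E11.40
401.1,ICD9,I10
401.9,ICD9,I10
272.4,ICD9,E78.5
272.0,ICD9,E78.00
530.81,ICD9,K21.9
311,ICD9,F32.9
300.00,ICD9,F41.9
493.90,ICD9,J45.909
477.9,ICD9,J30.9
786.2,ICD9,R05
724.2,ICD9,M54.5
719.46,ICD9,M25.569
268.9,ICD9,E55.9
278.00,ICD9,E66.9
285.9,ICD9,D64.9
244.9,ICD9,E03.9
715.90,ICD9,M19.90
V70.0,ICD9,Z00.00
V04.81,ICD9,Z23
44054006,SNOMED,E11.9
38341003,SNOMED,I10
55822004,SNOMED,E78.5
235595009,SNOMED,K21.9
35489007,SNOMED,F32.9
48694002,SNOMED,F41.9
195967001,SNOMED,J45.909
61582004,SNOMED,J30.9
49727002,SNOMED,R05
279039007,SNOMED,M54.5
57676002,SNOMED,M25.50
34713006,SNOMED,E55.9
414916001,SNOMED,E66.9
271737000,SNOMED,D64.9
40930008,SNOMED,E03.9
396275006,SNOMED,M19.90
185349003,SNOMED,Z00.00
571611000119101,SNOMED,Z23
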