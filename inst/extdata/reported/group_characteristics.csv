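axis,level,concordant,discordant,nonreporting
total,total,4344600,378060,1132220
age,<18,305350,46830,84990
age,18-64,2491460,248000,715970
age,>=65,1547780,83240,331270
sex,male,1944320,163120,509220
sex,female,2397990,214560,619120
svi,"[0,25]",987490,67420,247200
svi,"(25,50]",1089060,78480,246370
svi,"(50,75]",992050,88410,245270
svi,"(75,100]",642060,88920,205250
ruca,metropolitan,2960550,271680,839610
ruca,micropolitan,718380,56600,144890
ruca,small town,412260,30690,81250
ruca,rural,226290,16320,48950
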