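study_id,country,region,year_start,year_end,matrix,smoking,analyte,n,mean,median,q1,q3,min,max,sd,lod,lod_unknown,unit,mean_age,pct_male,source,excluded_flag,exclusion_reason
LH,SE,north,1991,1996,blood,nonsmoker,AAVal,70,,31,,,,,,,FALSE,pmol_per_g_Hb,,,published,TRUE,multi-year sampling without yearly means
LH,SE,north,1991,1996,blood,smoker,AAVal,72,,152,,,,,,,FALSE,pmol_per_g_Hb,,,published,TRUE,multi-year sampling without yearly means
MOS,ES,south,1992,2000,blood,nonsmoker,AAVal,417,,43.1,,,,,,,FALSE,pmol_per_g_Hb,,0,published,TRUE,multi-year sampling without yearly means
MOS,ES,south,1992,2000,blood,nonsmoker,GAVal,417,,35.4,,,,,,,FALSE,pmol_per_g_Hb,,0,published,TRUE,multi-year sampling without yearly means
AV1,SE,north,1999,2000,blood,nonsmoker,AAVal,68,,39,,,,,,,FALSE,pmol_per_g_Hb,,,published,TRUE,multi-year sampling without yearly means
AV1,SE,north,1999,2000,blood,nonsmoker,GAVal,68,,67,,,,,,,FALSE,pmol_per_g_Hb,,,published,TRUE,multi-year sampling without yearly means
TS1,DE,central_west,2001,2001,blood,nonsmoker,AAVal,25,,21,,,,,,,FALSE,pmol_per_g_Hb,34,88,published,FALSE,
TS1,DE,central_west,2001,2001,blood,smoker,AAVal,47,,85,,,,,,,FALSE,pmol_per_g_Hb,34,88,published,FALSE,
MU,DE,central_west,2002,2002,urine_24h,nonsmoker,AAMA,60,41.6,,,,,,,,FALSE,ug_per_L,,38.3,published,TRUE,24 h urine collection not comparable to spot urine
MU,DE,central_west,2002,2002,urine_24h,smoker,AAMA,60,107.3,,,,,,,,FALSE,ug_per_L,,38.3,published,TRUE,24 h urine collection not comparable to spot urine
MU,DE,central_west,2002,2002,urine_24h,nonsmoker,GAMA,60,8.7,,,,,,,,FALSE,ug_per_L,,38.3,published,TRUE,24 h urine collection not comparable to spot urine
MU,DE,central_west,2002,2002,urine_24h,smoker,GAMA,60,15.0,,,,,,,,FALSE,ug_per_L,,38.3,published,TRUE,24 h urine collection not comparable to spot urine
MU,DE,central_west,2002,2002,blood,nonsmoker,AAVal,60,27.6,,,,,,,,FALSE,pmol_per_g_Hb,,38.3,published,TRUE,companion record of excluded 24 h-urine study
MU,DE,central_west,2002,2002,blood,smoker,AAVal,60,81.8,,,,,,,,FALSE,pmol_per_g_Hb,,38.3,published,TRUE,companion record of excluded 24 h-urine study
SC,FR,central_west,,,blood,nonsmoker,AAVal,52,2753,,,,,,,,FALSE,pmol_per_L,,42.6,published,TRUE,no sampling year reported
SC,FR,central_west,,,blood,nonsmoker,GAVal,52,2334,,,,,,,,FALSE,pmol_per_L,,42.6,published,TRUE,no sampling year reported
TS2,DE,central_west,2003,2003,blood,nonsmoker,AAVal,13,18,,,,,,,,FALSE,pmol_per_g_Hb,35,23.0,published,FALSE,
TS2,DE,central_west,2003,2003,blood,smoker,AAVal,16,80,,,,,,,,FALSE,pmol_per_g_Hb,35,23.0,published,FALSE,
TS2,DE,central_west,2003,2003,blood,nonsmoker,GAVal,13,17,,,,,,,,FALSE,pmol_per_g_Hb,35,23.0,published,FALSE,
TS2,DE,central_west,2003,2003,blood,smoker,GAVal,16,53,,,,,,,,FALSE,pmol_per_g_Hb,35,23.0,published,FALSE,
BK,DE,central_west,2003,2003,blood,nonsmoker,AAVal,857,28.2,,,,,,,,FALSE,pmol_per_g_Hb,41.6,46.9,published,FALSE,
BK,DE,central_west,2003,2003,blood,smoker,AAVal,148,82.6,,,,,,,,FALSE,pmol_per_g_Hb,41.6,46.9,published,FALSE,
MB,DE,central_west,2003,2003,spot_urine,nonsmoker,AAMA,16,,29,,,,,,,FALSE,ug_per_L,25.5,31.2,published,FALSE,
MB,DE,central_west,2003,2003,spot_urine,smoker,AAMA,13,,127,,,,,,,FALSE,ug_per_L,25.5,31.2,published,FALSE,
MB,DE,central_west,2003,2003,spot_urine,nonsmoker,GAMA,16,,5,,,,,,,FALSE,ug_per_L,25.5,31.2,published,FALSE,
MB,DE,central_west,2003,2003,spot_urine,smoker,GAMA,13,,19,,,,,,,FALSE,ug_per_L,25.5,31.2,published,FALSE,
TS3,DE,central_west,2003,2003,blood,nonsmoker,AAVal,92,,29.9,,,,,,,FALSE,pmol_per_g_Hb,35,21.7,published,FALSE,
TS3,DE,central_west,2003,2003,blood,nonsmoker,GAVal,92,,35.2,,,,,,,FALSE,pmol_per_g_Hb,35,21.7,published,FALSE,
EH,DE,central_west,2003,2003,spot_urine,nonsmoker,AAMA,91,,29,,,,229,,,TRUE,ug_per_L,36,49.4,published,FALSE,
EH,DE,central_west,2003,2003,spot_urine,nonsmoker,GAMA,91,,7,,,,,,,FALSE,ug_per_L,36,49.4,published,FALSE,
EH,DE,central_west,2003,2003,blood,nonsmoker,AAVal,91,,30,,,15,71,,,FALSE,pmol_per_g_Hb,36,49.4,published,FALSE,
EH,DE,central_west,2003,2003,blood,nonsmoker,GAVal,91,,34,,,,,,,FALSE,pmol_per_g_Hb,36,49.4,published,FALSE,
TB,NO,north,2005,2005,blood,nonsmoker,AAVal,44,38.4,,,,,,,,FALSE,pmol_per_g_Hb,45,45.4,published,FALSE,
TB,NO,north,2005,2005,blood,smoker,AAVal,6,154,,,,,,,,FALSE,pmol_per_g_Hb,45,45.4,published,FALSE,
TB,NO,north,2005,2005,blood,nonsmoker,GAVal,44,19.6,,,,,,,,FALSE,pmol_per_g_Hb,45,45.4,published,FALSE,
TB,NO,north,2005,2005,blood,smoker,GAVal,6,76.6,,,,,,,,FALSE,pmol_per_g_Hb,45,45.4,published,FALSE,
UH,DE,central_west,2007,2007,spot_urine,nonsmoker,AAMA,110,57.8,,,,,,,,FALSE,ug_per_L,5.5,57.2,published,FALSE,
UH,DE,central_west,2007,2007,spot_urine,nonsmoker,GAMA,110,18.3,,,,,,,,FALSE,ug_per_L,5.5,57.2,published,FALSE,
HS,SE,north,2007,2007,blood,nonsmoker,AAVal,81,28,,,,,,,,FALSE,pmol_per_g_Hb,30,0,published,FALSE,
HS,SE,north,2007,2007,blood,smoker,AAVal,6,110,,,,,,,,FALSE,pmol_per_g_Hb,30,0,published,FALSE,
HS,SE,north,2007,2007,blood,nonsmoker,GAVal,81,22,,,,,,,,FALSE,pmol_per_g_Hb,30,0,published,FALSE,
HS,SE,north,2007,2007,blood,smoker,GAVal,6,102,,,,,,,,FALSE,pmol_per_g_Hb,30,0,published,FALSE,
EKK,DE,central_west,2008,2008,spot_urine,nonsmoker,AAMA,67,,39,,,,,,,FALSE,ug_per_L,35.5,32.8,published,FALSE,
EKK,DE,central_west,2008,2008,spot_urine,smoker,AAMA,67,,121,,,,,,,FALSE,ug_per_L,35.5,32.8,published,FALSE,
EKK,DE,central_west,2008,2008,spot_urine,nonsmoker,GAMA,67,,9,,,,,,,FALSE,ug_per_L,35.5,32.8,published,FALSE,
EKK,DE,central_west,2008,2008,spot_urine,smoker,GAMA,67,,25,,,,,,,FALSE,ug_per_L,35.5,32.8,published,FALSE,
TDS,NO,north,2007,2009,blood,nonsmoker,AAVal,79,31,,,,,,,,FALSE,pmol_per_g_Hb,30,0,published,FALSE,
TDS,NO,north,2007,2009,blood,nonsmoker,GAVal,79,23,,,,,,,,FALSE,pmol_per_g_Hb,30,0,published,FALSE,
AV2,SE,north,2011,2011,blood,nonsmoker,AAVal,10,59,,,,,,,,FALSE,pmol_per_g_Hb,46,50,published,FALSE,
AV2,SE,north,2011,2011,blood,nonsmoker,GAVal,10,72,,,,,,,,FALSE,pmol_per_g_Hb,46,50,published,FALSE,
HM,PL,central_west,2012,2012,morning_urine,nonsmoker,AAMA,78,,18.9,,,,,,,FALSE,ug_per_L,30,0,published,FALSE,
HM,PL,central_west,2012,2012,morning_urine,smoker,AAMA,5,,168,,,,,,,FALSE,ug_per_L,30,0,published,FALSE,
HM,PL,central_west,2012,2012,morning_urine,nonsmoker,GAMA,78,,6.8,,,,,,,FALSE,ug_per_L,30,0,published,FALSE,
HM,PL,central_west,2012,2012,morning_urine,smoker,GAMA,5,,27.7,,,,,,,FALSE,ug_per_L,30,0,published,FALSE,
KG,DE,central_west,2015,2015,urine_12h,nonsmoker,AAMA,20,312,,,,,,,,FALSE,nmol_per_day,26,50,published,FALSE,
KG,DE,central_west,2015,2015,urine_12h,nonsmoker,GAMA,20,45,,,,,,,,FALSE,nmol_per_day,26,50,published,FALSE,
KG2,DE,central_west,2015,2015,blood,nonsmoker,AAVal,6,24.5,,,,,,,,FALSE,pmol_per_g_Hb,,100,published,FALSE,
KG2,DE,central_west,2015,2015,blood,nonsmoker,GAVal,6,17.2,,,,,,,,FALSE,pmol_per_g_Hb,,100,published,FALSE,
GF,IT,south,2017,2017,urine_24h,nonsmoker,AAMA,38,,142,,,,,,,FALSE,ug_per_g_creatinine,46,89.4,published,TRUE,24 h urine and creatinine-based unit
GF,IT,south,2017,2017,urine_24h,smoker,AAMA,22,,405,,,,,,,FALSE,ug_per_g_creatinine,46,89.4,published,TRUE,24 h urine and creatinine-based unit
GF,IT,south,2017,2017,urine_24h,nonsmoker,GAMA,38,,1.3,,,,,,,FALSE,ug_per_g_creatinine,46,89.4,published,TRUE,24 h urine and creatinine-based unit
GF,IT,south,2017,2017,urine_24h,smoker,GAMA,22,,3.2,,,,,,,FALSE,ug_per_g_creatinine,46,89.4,published,TRUE,24 h urine and creatinine-based unit
GS,DE,central_west,2015,2017,spot_urine,nonsmoker,AAMA,2211,95.33,,,,,,,,FALSE,ug_per_L,10.4,51.6,published,TRUE,overlaps the aligned German survey dataset
GS,DE,central_west,2015,2017,spot_urine,smoker,AAMA,48,242.4,,,,,,,,FALSE,ug_per_L,10.4,51.6,published,TRUE,overlaps the aligned German survey dataset
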