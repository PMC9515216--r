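age_group,total,train,val,test,male,female
4-10,2599,1822,393,384,1264,1335
11-15,7652,5354,1148,1150,3072,4580
16-20,4591,3211,690,690,1713,2878
21-25,3044,2137,454,453,815,2229
26-30,1452,1020,210,222,297,1155
31-35,577,408,86,83,102,475
36-40,259,190,37,32,39,220
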