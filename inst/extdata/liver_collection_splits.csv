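split,tumor_type,training,test
1,cyst,2578,667
1,hcc,1086,278
1,hemangioma,1376,410
1,metastasis,1017,195
2,cyst,2562,683
2,hcc,1064,300
2,hemangioma,1437,349
2,metastasis,1017,195
3,cyst,2608,637
3,hcc,1059,305
3,hemangioma,1432,354
3,metastasis,958,254
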