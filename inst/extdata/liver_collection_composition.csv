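tumor_type,images,cases
cyst,3245,925
hcc,1364,304
hemangioma,1786,562
metastasis,1212,205
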