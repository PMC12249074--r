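study_alias,n
head,22051
neck,1378
chest,40810
abdomen,14541
pelvis,603
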