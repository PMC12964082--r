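"study_id","mating","sex","n_r","n_l","pairs"
"synth_sex","rmrf","f",3561,977,3000
"synth_sex","rmrf","m",3376,1086,3000
"synth_sex","rmlf","f",299,86,260
"synth_sex","rmlf","m",296,99,260
"synth_sex","lmrf","f",233,113,240
"synth_sex","lmrf","m",220,154,240
"synth_sex","lmlf","f",38,13,30
"synth_sex","lmlf","m",30,9,30
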