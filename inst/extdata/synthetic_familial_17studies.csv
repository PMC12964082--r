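"study_id","rxr_r","rxr_l","mix_r","mix_l","lxl_r","lxl_l","pairs_rxr","pairs_mix","pairs_lxl","m_p"
"synth_01",5998,437,1254,312,73,26,2145,522,33,0.108888888888889
"synth_02",3284,286,915,258,42,15,1190,391,19,0.1340625
"synth_03",1811,367,967,296,106,53,726,421,53,0.219583333333333
"synth_04",1982,157,421,104,23,13,713,175,12,0.110555555555556
"synth_05",1587,144,277,65,16,11,577,114,9,0.0942857142857143
"synth_06",1134,99,183,72,9,3,411,85,4,0.093
"synth_07",863,76,215,37,7,2,313,84,3,0.1125
"synth_08",454,29,301,50,54,12,161,117,22,0.268333333333333
"synth_09",578,61,86,22,2,1,213,36,1,0.076
"synth_10",270,54,165,54,45,12,108,73,19,0.2775
"synth_11",294,78,44,28,3,3,124,24,2,0.0933333333333333
"synth_12",297,30,45,18,0,0,109,21,0,0.0807692307692308
"synth_13",183,30,80,19,14,4,71,33,6,0.204545454545455
"synth_14",217,14,56,13,0,0,77,23,0,0.115
"synth_15",203,13,38,13,2,1,72,17,1,0.105555555555556
"synth_16",144,48,33,15,0,0,64,16,0,0.1
"synth_17",127,32,35,16,0,0,53,17,0,0.121428571428571
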