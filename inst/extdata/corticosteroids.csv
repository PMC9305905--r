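study_id,events_t,total_t,events_c,total_c
DEXA-COVID 19,2,7,2,12
CoDEX,69,128,76,128
CAPE COVID,11,75,20,73
COVID STEROID,6,15,2,14
RECOVERY,95,324,283,683
REMAP-CAP,26,105,29,92
Steroids-SARI,13,24,13,23
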