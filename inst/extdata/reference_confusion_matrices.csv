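modality,row,relaxed,sad,happy,angry
eeg,relaxed,6,1,2,0
eeg,sad,0,15,6,1
eeg,happy,4,2,33,1
eeg,angry,1,2,1,9
gsr,relaxed,7,1,2,1
gsr,sad,0,18,5,0
gsr,happy,2,3,29,5
gsr,angry,0,0,4,7
ppg,relaxed,7,0,4,0
ppg,sad,0,17,1,4
ppg,happy,2,2,35,2
ppg,angry,0,3,0,7
fused,relaxed,7,0,1,0
fused,sad,1,16,3,2
fused,happy,1,6,35,2
fused,angry,0,0,1,9
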