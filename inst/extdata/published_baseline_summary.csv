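score,wave,mean,sd,min,q1,median,q3,max,floor_pct,ceiling_pct
utility_japanese,baseline,0.777,0.163,0.179,0.686,0.740,0.843,1.000,0.0,24.8
utility_uk,baseline,0.785,0.200,-0.283,0.721,0.777,0.906,1.000,0.0,24.8
FACTB,baseline,103.0,20.8,45,90,104,119,140,0.0,0.0
FACTG,baseline,81.3,16.9,35,71,83,95,108,0.0,1.7
TOI,baseline,62.8,14.9,16,53,64,74,89,0.0,0.0
PWB,baseline,21.1,6.0,1,18,22,26,28,0.0,12.2
SWB,baseline,22.2,6.1,0,20,24,27,28,1.3,21.0
EWB,baseline,18.0,4.7,4,15,19,22,24,0.0,11.8
FWB,baseline,20.0,6.7,0,16,21,26,28,1.3,13.0
BCS,baseline,21.7,6.1,5,17,22,27,36,0.0,0.4
utility_japanese,followup,0.758,0.160,0.052,0.649,0.740,0.829,1.000,0.0,20.8
utility_uk,followup,0.770,0.193,-0.283,0.679,0.768,0.879,1.000,0.0,20.8
FACTB,followup,101.2,22.2,27,85,103,118,140,0.0,0.0
FACTG,followup,79.6,18.0,20,67,82,94,108,0.0,2.3
TOI,followup,61.6,15.8,9,51,63,74,89,0.0,0.0
PWB,followup,21.0,6.1,0,17,22,26,28,0.9,11.8
SWB,followup,21.7,5.5,4,18,22,27,28,0.0,18.1
EWB,followup,17.9,4.7,3,15,19,21,24,0.0,11.3
FWB,followup,19.0,6.9,2,14,21,25,28,0.0,9.0
BCS,followup,21.6,6.2,7,17,22,26,35,0.0,0.0
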