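experiment,assay,genotype,n_larvae,approach_pre,avoid_pre,approach_post,avoid_post,approach_next_day,avoid_next_day
Gr63a1,innate,Gr63a1,44,831,745,NA,NA,NA,NA
DANi1>CsChrimson ATR+,innate,DANi1>CsChrimson,159,1714,4978,NA,NA,NA,NA
DANi1>CsChrimson ATR-,innate,DANi1>CsChrimson,16,256,614,NA,NA,NA,NA
Paired,reward_timing,DANi1>CsChrimson,64,561,1760,936,868,NA,NA
Offset After,reward_timing,DANi1>CsChrimson,20,288,757,316,305,NA,NA
Reverse Paired,reward_timing,DANi1>CsChrimson,29,315,1022,154,530,NA,NA
Offset Before,reward_timing,DANi1>CsChrimson,19,218,512,136,315,NA,NA
Paired ATR-,reward_timing,DANi1>CsChrimson,16,256,614,127,307,NA,NA
No Training,reward_timing,DANi1>CsChrimson,50,578,1599,479,1295,NA,NA
DAN w/o CO2,reward_timing,DANi1>CsChrimson,16,260,597,161,354,NA,NA
Driver ctrl,reward_timing,SS00864,17,110,289,158,358,NA,NA
Effector ctrl,reward_timing,UAS-CsChrimson,18,214,516,114,294,NA,NA
58E02>CsChrimson,reward_timing,58E02>CsChrimson,21,380,912,493,501,NA,NA
Forward Paired,extended_spacing,DANi1>CsChrimson,22,181,496,350,337,NA,NA
Backwards Paired,extended_spacing,DANi1>CsChrimson,18,181,438,124,320,NA,NA
Btw CO2,extended_spacing,DANi1>CsChrimson,23,272,652,165,283,NA,NA
6.5%,co2_concentration,DANi1>CsChrimson,19,361,568,319,290,NA,NA
8%,co2_concentration,DANi1>CsChrimson,27,256,567,295,255,NA,NA
15%,co2_concentration,DANi1>CsChrimson,19,170,368,249,233,NA,NA
18%,co2_concentration,DANi1>CsChrimson,64,561,1760,936,868,NA,NA
0 Cycles,dose_response,DANi1>CsChrimson,50,578,1599,479,1295,NA,NA
1 Cycles,dose_response,DANi1>CsChrimson,35,218,606,317,495,NA,NA
2 Cycles,dose_response,DANi1>CsChrimson,87,840,2552,1081,1292,NA,NA
3 Cycles,dose_response,DANi1>CsChrimson,31,310,930,686,686,NA,NA
4 Cycles,dose_response,DANi1>CsChrimson,32,245,712,493,511,NA,NA
5 Cycles,dose_response,DANi1>CsChrimson,63,863,2491,975,993,NA,NA
10 Cycles,dose_response,DANi1>CsChrimson,14,100,287,154,144,NA,NA
20 Cycles,dose_response,DANi1>CsChrimson,64,561,1760,936,868,NA,NA
2 Cycles Training,extinction,DANi1>CsChrimson,87,840,2552,1081,1292,NA,NA
2 Cycles Habituation + Training,extinction,DANi1>CsChrimson,30,385,1127,422,554,NA,NA
2 Cycles Training + Extinction,extinction,DANi1>CsChrimson,30,336,946,375,793,NA,NA
3 Cycles Training,extinction,DANi1>CsChrimson,30,308,924,675,679,NA,NA
3 Cycles Habituation + Training,extinction,DANi1>CsChrimson,18,222,591,260,294,NA,NA
3 Cycles Training + Extinction,extinction,DANi1>CsChrimson,26,279,695,195,416,NA,NA
4 Cycles Training,extinction,DANi1>CsChrimson,30,225,659,490,502,NA,NA
4 Cycles Habituation + Training,extinction,DANi1>CsChrimson,18,239,701,372,352,NA,NA
4 Cycles Training + Extinction,extinction,DANi1>CsChrimson,27,384,1074,394,475,NA,NA
5 Cycles Training,extinction,DANi1>CsChrimson,63,863,2491,975,993,NA,NA
6 Cycles Habituation + Training,extinction,DANi1>CsChrimson,19,266,758,367,324,NA,NA
6 Cycles Training + Extinction,extinction,DANi1>CsChrimson,18,253,687,309,317,NA,NA
10 Cycles Training,extinction,DANi1>CsChrimson,14,100,287,154,144,NA,NA
10 Cycles Habituation + Training,extinction,DANi1>CsChrimson,30,406,1193,607,503,NA,NA
10 Cycles Training + Extinction,extinction,DANi1>CsChrimson,30,426,1180,401,386,NA,NA
20x,overnight,DANi1>CsChrimson,28,380,1172,509,499,459,409
20x (Only Test Next Day),overnight,DANi1>CsChrimson,14,224,768,NA,NA,296,250
5x,overnight,DANi1>CsChrimson,29,472,1427,488,480,404,461
2x,overnight,DANi1>CsChrimson,42,514,1537,594,693,201,548
2x (Only Test Next Day),overnight,DANi1>CsChrimson,22,209,696,NA,NA,213,283
No Train,overnight,DANi1>CsChrimson,20,316,889,187,544,104,337
RP 20x,overnight,DANi1>CsChrimson,21,282,905,121,430,109,361
Ext Post-Train,overnight,DANi1>CsChrimson,23,181,477,NA,NA,158,365
Ext Pre-Test,overnight,DANi1>CsChrimson,31,417,1002,NA,NA,385,429
M 20x (CXM+/ATR+),protein_synthesis,DANi1>CsChrimson,20,110,282,252,237,237,272
M 20x (CXM-/ATR+),protein_synthesis,DANi1>CsChrimson,17,159,419,271,236,228,235
S 20x (CXM+/ATR+),protein_synthesis,DANi1>CsChrimson,23,191,486,NA,NA,150,316
S 20x (CXM-/ATR+),protein_synthesis,DANi1>CsChrimson,20,197,511,NA,NA,254,264
M 10x (CXM+/ATR+),protein_synthesis,DANi1>CsChrimson,23,136,345,NA,NA,331,344
M 10x (CXM-/ATR+),protein_synthesis,DANi1>CsChrimson,20,175,454,NA,NA,419,375
M 10x HS,creb,DANi1>hs-dCREB2-b;CsChrimson,21,175,434,392,370,253,246
M 10x No HS,creb,DANi1>hs-dCREB2-b;CsChrimson,22,248,656,367,353,451,490
S 10x HS,creb,DANi1>hs-dCREB2-b;CsChrimson,24,172,420,68,156,153,339
S 10x No HS,creb,DANi1>hs-dCREB2-b;CsChrimson,22,294,736,212,184,335,352
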