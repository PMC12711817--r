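Participant,Sex,Age,Weight,F1,F2,F3.1,F3.2,F3.3,F3.4,F4,F5,F1_after,F2_after,F3.1_after,F3.2_after,F3.3_after,F3.4_after,F4_after,F5_after,flag_note
P1,M,55,70,129,122,90,88,167,103,57,23,117,101,90,129,163,103,231,22,
P2,F,48,60,126,89,77,117,153,110,56,23,103,137,77,125,146,110,227,22,
P3,M,39,72,86,140,93,127,144,102,58,23,94,152,93,77,172,102,234,22,
P4,F,52,66,126,82,99,88,146,111,56,23,96,101,99,126,142,111,227,22,
P5,M,48,80,103,126,85,79,133,107,56,23,83,89,85,97,166,107,227,22,
P6,F,35,76,86,130,98,106,135,104,60,23,85,122,98,78,167,104,240,22,
P7,F,25,58,98,105,82,114,155,121,52,23,105,133,82,91,155,121,215,22,
P8,M,36,74,121,152,90,128,134,135,51,23,84,185,90,119,179,135,214,22,
P9,M,28,78,103,152,98,107,166,130,58,23,116,124,98,98,179,130,234,22,
P10,F,56,60,111,125,96,119,142,110,57,23,92,140,96,107,165,110,230,22,
P11,F,47,65,103,82,87,117,155,135,55,23,105,136,87,97,142,135,225,22,
P12,M,66,75,121,143,78,85,159,126,53,23,109,97,78,119,175,126,219,22,
P13,M,26,68,97,92,97,108,163,107,57,23,113,126,97,91,147,107,232,22,
P14,F,40,76,122,101,95,123,131,116,54,23,81,144,95,120,152,116,222,22,
P15,M,49,79,81,109,92,83,176,136,54,23,126,94,92,71,157,136,223,22,
P16,M,56,83,86,137,78,103,131,137,54,23,81,119,78,77,172,137,221,22,
P17,F,60,75,88,140,92,72,177,139,53,23,127,80,92,80,173,139,218,22,
P18,F,31,70,87,119,79,84,134,116,55,23,84,95,79,78,162,116,226,22,
P19,M,42,83,86,118,75,92,154,101,52,23,104,106,75,77,161,101,217,22,
P20,M,49,85,112,149,94,79,148,103,59,23,98,89,94,108,178,103,237,22,
P21,F,35,71,104,117,83,106,144,127,57,23,94,123,83,99,161,127,230,22,
P22,M,59,79,94,134,90,109,134,124,53,23,84,127,90,86,170,124,220,22,
P23,F,61,67,82,78,99,83,142,134,59,23,92,152,98,73,140,134,238,22,F2*;F3.1*;F2_after*
P24,F,50,79,109,99,86,108,161,134,51,23,111,126,86,105,151,134,212,22,
P25,M,44,81,109,121,78,129,164,112,59,23,114,151,78,105,163,112,236,22,
P26,F,39,66,104,122,86,113,179,130,53,23,129,132,86,99,163,130,219,22,
P27,M,36,77,124,132,81,113,175,137,56,23,125,131,81,123,169,137,228,22,
P28,F,64,72,97,80,98,95,143,102,53,23,93,146,97,90,143,102,219,22,F2*;F3.1*;F2_after*
P29,M,24,72,89,105,84,104,176,114,56,23,126,121,84,81,154,114,227,22,
P30,M,29,80,109,132,81,105,155,134,60,23,105,121,81,105,169,134,239,22,
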