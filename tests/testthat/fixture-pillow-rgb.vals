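136,188,212,185,164,247,135,250,71,129,214,190,22,218,160,16,49,45,187,10,206,153,6,103,33,151,77,161,40,74,167,111,226,5,90,54,255,163,210,76,7,34,144,5,224,111,162,203,97,201,161,9,57,231,120,30,65,35,188,85,112,98,151,31,127,214,230,117,201,215,97,129,218,14,58,179,54,58,42,99,197,215,123,254,18,110,115,194,250,69,111,233,170,230,23,120,141,214,44,52,34,120,34,222,215,112,40,163,22,76,56,109,39,177,101,177,120,28,100,73,134,16,195,248,77,49,183,61,133,166,114,59,129,139,141,24,75,246,161,184,113,206,77,89,181,94,76,149,212,118,68,210,151,120,83,237,24,187,83,176,236,66,216,154,199,230,173,187,199,120,110,173,168,9,157,35,62,80,44,219,98,6,219,68,75,76,79,46,129,243,88,8,113,200,223,197,195,121,145,47,73,20,204,64,38,47,164,217,215,34,84,14,222,228,195,148,205,194,4,194,23,105,22,92,99,145,25,5,198,172,129,245,93,105,16,116,1,138,230,22,145,130,35,42,123,49,17,206,253,188,103,70,86,19,139,18,68,129,171,121,224,142,144,149,36,131,131,121,61,94,183,200,187,62,183,85,110,204,81,190,11,139,48,22,199,81,92,177,205,189,30,90,235,207,1,229,51,131,83,218,136,41,58,99,132,208,41,207,159,221,143,225,14,115,150,170,43,203,42,168,223,171,127,117,178,23,68,60,190,129,59,125,180,136,172,186,147,158,175,114,220,69,223,174,241,194,110,210,1,175,227,163,200,40,179,2,219,252,154,236,140,46,86,25,142,33,227,209,21,218,227,62,134,64,250,15,190,189,66,69,142,179,181,85,194,206,240,199,220,204,53,213,123,71,248,72,68,49,211,136,183,53,196,45,105,18,111,235,217,13,182,70,211,125,41,213,13,5,199,251,251,64,103,180,242,105,58,106,126,219,147,239,193,183,160,115,23,83,131,9,49,9,124,223,167,59,62,195,119,209,238,74,203,201,78,76,90,209,202,194,111,114,122,215,115,218,45,104,22,22,113,85,185,31,240,49,244,200,141,31,194,32,81,54,160,19,233,18,109,29,47,159,219,249,81,137,139,52,220,224,170,138,51,93,0,126,34,17,127,174,244,73,184,116,170,8,182,41,23,127,226,234,213,83,183,87,203,227,235,128,249,147,211,48,56,6,93,167,207,65,51,236,191,247,174,131,146,177,70,153,155,176,28,146,227,228,42,137,63,163,221,133,119,14,83,102,16,140,187,57,24,198,225,63,7,13,237,237,184,36,11,175,247,60,23,144,245,198,249,20,162,16,93,199,107,23,117,70,181,5,90,88,44,194,174,191,116,51,111,247,78,234
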