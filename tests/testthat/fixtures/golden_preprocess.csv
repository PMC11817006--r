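105,110,121,133,133,122,113,113,121,131,137,139,140,139,137,135
108,112,118,124,124,116,111,113,122,132,137,139,139,138,135,131
113,115,117,117,116,112,110,113,123,133,137,138,138,135,130,124
117,117,117,115,112,109,109,113,123,132,136,137,135,130,121,114
120,119,117,114,111,109,109,114,123,130,134,134,131,122,109,100
122,121,119,116,112,111,112,116,122,127,130,130,125,111,94,86
125,124,122,119,117,116,117,119,122,125,126,125,118,100,82,75
128,127,125,124,122,121,121,122,123,124,124,122,114,93,75,69
129,129,128,126,125,124,124,125,125,125,124,122,115,96,77,70
130,130,129,128,127,126,126,126,126,126,125,123,119,108,90,81
130,130,129,128,128,128,128,128,127,126,125,123,121,117,110,105
130,129,129,129,129,129,129,129,128,126,125,123,122,121,121,121
129,129,128,129,130,131,131,130,128,125,123,121,121,122,124,124
129,128,128,129,131,132,133,131,127,121,117,116,118,120,122,122
130,128,128,130,132,134,135,132,123,113,109,109,112,116,118,118
131,129,129,130,133,136,136,133,121,108,104,105,109,113,115,115
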