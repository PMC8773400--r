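classes,tn,fn,fp,tp
0,238818,173,131,78
"0,1",238727,123,222,128
"0,1,2",238632,89,317,162
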