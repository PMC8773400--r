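dataset,date,day,r,n_edges,n_nodes
card,2020-11-10,2,0.8771,2214,736
card,2020-11-11,3,0.8616,1395,736
card,2020-11-12,4,0.8527,957,736
card,2020-11-13,5,0.8960,942,736
card,2020-11-14,6,0.9160,714,736
case_investigation,2020-11-09,1,0.7500,16,65
case_investigation,2020-11-10,2,0.4615,13,65
case_investigation,2020-11-11,3,0.6667,12,65
case_investigation,2020-11-12,4,0.6154,13,65
case_investigation,2020-11-13,5,0.7692,13,65
case_investigation,2020-11-14,6,0.5455,11,65
case_investigation,2020-11-15,7,0.6667,12,65
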