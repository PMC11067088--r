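"mqtl_id","lg","position_cm","pve_pct","start_bp","stop_bp"
"CaMQAST1.1","CaLG01",5.87,42,432233,702233
"CaMQAST1.7","CaLG01",71.25,6,16552817,17492638
"CaMQAST1.9","CaLG01",134.68,7,14038103,13991104
"CaMQAST2.2","CaLG02",69.66,14,30346113,24093127
"CaMQAST3.3","CaLG03",92.01,7,28996181,32662861
"CaMQAST3.5","CaLG03",195.61,2,28459930,22008087
"CaMQAST3.8","CaLG03",242.74,7,32748128,32661055
"CaMQAST4.1","CaLG04",20.09,15,6613796,6841834
"CaMQAST4.2","CaLG04",71.9,5,28636088,24013381
"CaMQAST4.3","CaLG04",82.05,8,38370902,37349212
"CaMQAST4.4","CaLG04",85.96,66,38960478,40358494
"CaMQAST5.2","CaLG05",16.36,5,5404385,6300360
"CaMQAST5.7","CaLG05",80.3,2,26477751,28239535
"CaMQAST6.2","CaLG06",43.68,1,57632163,57761758
"CaMQAST6.4","CaLG06",86.01,33,8706550,2214178
"CaMQAST6.7","CaLG06",115.52,2,37280189,39781068
"CaMQAST6.9","CaLG06",158.75,1,52417747,53683753
"CaMQAST7.3","CaLG07",30.02,5,10050020,11192667
"CaMQAST7.5","CaLG07",44.84,5,15099099,16104217
"CaMQAST7.7","CaLG07",58.07,35,1086709,20579963
"CaMQAST7.8","CaLG07",71.07,11,23439225,25218332
"CaMQAST8.2","CaLG08",13.94,22,4717179,4980923
"CaMQAST8.3","CaLG08",22.83,4,7193960,8293716
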