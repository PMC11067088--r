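"mqtl_id","lg","position_cm","ci_lo_cm","ci_hi_cm","pve_pct","flank_left","flank_right"
"CaMQAST1.1","CaLG01",5.87,5.47,6.27,42,"S1_432233","S1_702233"
"CaMQAST1.2","CaLG01",13.02,12.695,13.345,8,"SNP5","AX-123644833"
"CaMQAST1.3","CaLG01",15.83,15.695,15.965,1,"DArT1786","DArT1798"
"CaMQAST1.4","CaLG01",27.9,27.76,28.04,5,"S1_2513914","S1_2649906"
"CaMQAST1.5","CaLG01",40.6,40.52,40.68,5,"1120_1","S1_6880666"
"CaMQAST1.6","CaLG01",56.32,56.175,56.465,2,"TA116","TA43"
"CaMQAST1.7","CaLG01",71.25,69.875,72.625,6,"S1_16552817","S1_17492638"
"CaMQAST1.8","CaLG01",78.3,78.23,78.37,23,"H5A08","CKaM1904"
"CaMQAST1.9","CaLG01",134.68,134.45,134.91,7,"S1_14038103","S1_13991104"
"CaMQAST2.1","CaLG02",65.31,64.57,66.05,6,"OPZ03943","M10_MtmtGEN10_03_1"
"CaMQAST2.2","CaLG02",69.66,68.07,71.25,14,"CKaM1101","S2_24093127"
"CaMQAST2.3","CaLG02",106.9,106.835,106.965,18,"S2_35795497","S2_35875671"
"CaMQAST3.1","CaLG03",14.35,12.955,15.745,7,"3113_3","3068_3"
"CaMQAST3.2","CaLG03",43.69,42,45.38,12,"2584_3","S3_15583265"
"CaMQAST3.3","CaLG03",92.01,86.72,97.3,7,"S3_28996181","S3_32662861"
"CaMQAST3.4","CaLG03",160.5,153.37,167.63,2,"AX-123621900","AX-123621911"
"CaMQAST3.5","CaLG03",195.61,188.89,202.33,2,"CKAM0554","Ca3_22008087"
"CaMQAST3.6","CaLG03",212.07,209.655,214.485,4,"SCAF10_699507","Ca3_31267675"
"CaMQAST3.7","CaLG03",228.43,227.425,229.435,56,"NCPGR12","SCAF8210_1451"
"CaMQAST3.8","CaLG03",242.74,242.055,243.425,7,"CaM0610","TOG912320"
"CaMQAST4.1","CaLG04",20.09,19.755,20.425,15,"S4_6613796","S4_6841834"
"CaMQAST4.2","CaLG04",71.9,71.845,71.955,5,"H5A04","S4_24013381"
"CaMQAST4.3","CaLG04",82.05,81.89,82.21,8,"Ca4_38370902","Ca4_37349212"
"CaMQAST4.4","CaLG04",85.96,85.92,86,66,"TOG900323","TOG906662"
"CaMQAST5.1","CaLG05",3.71,3.66,3.76,33,"S5_31260243","5690_5"
"CaMQAST5.2","CaLG05",16.36,15.28,17.44,5,"S5_5404385","S5_6300360"
"CaMQAST5.3","CaLG05",20.31,19.115,21.505,2,"cpPb-682328","5426_5"
"CaMQAST5.4","CaLG05",29.02,28.35,29.69,21,"cpPb-326684","S5_10406613"
"CaMQAST5.5","CaLG05",56.21,52.015,60.405,2,"S5_40439514","AX-123631517"
"CaMQAST5.6","CaLG05",60.32,59.87,60.77,3,"CAMCAG04","AX-123631517"
"CaMQAST5.7","CaLG05",80.3,78.03,82.57,2,"S5_26477751","S5_28239535"
"CaMQAST5.8","CaLG05",107.96,107.4,108.52,32,"S5_36251841","S5_36672164"
"CaMQAST6.1","CaLG06",9.94,9.005,10.875,29,"7704_6","S6_3985519"
"CaMQAST6.2","CaLG06",43.68,43.66,43.7,1,"AX-123642585","AX-123663334"
"CaMQAST6.3","CaLG06",78.9,77.635,80.165,1,"SCAF11_4875713","OPC06_1"
"CaMQAST6.4","CaLG06",86.01,85.465,86.555,33,"CKaM1351","Ca6_2214178"
"CaMQAST6.5","CaLG06",87.96,87.905,88.015,13,"AX-123634395","AGL76"
"CaMQAST6.6","CaLG06",101.12,100.02,102.22,1,"S6_33334977","S6_34480990"
"CaMQAST6.7","CaLG06",115.52,113.61,117.43,2,"S6_37280189","S6_39781068"
"CaMQAST6.8","CaLG06",134.9,133.63,136.17,7,"Pgd1","S6_45695043"
"CaMQAST6.9","CaLG06",158.75,156.99,160.51,1,"S6_52417747","S6_53683753"
"CaMQAST6.10","CaLG06",191.38,189.12,193.64,1,"CaM0399","AX-123640392"
"CaMQAST7.1","CaLG07",9.67,8.435,10.905,4,"8180_7","S7_4411515"
"CaMQAST7.2","CaLG07",18.47,18.07,18.87,14,"8045_7","S7_6970143"
"CaMQAST7.3","CaLG07",30.02,28.425,31.615,5,"S7_10050020","S7_11192667"
"CaMQAST7.4","CaLG07",40.77,39.07,42.47,13,"CAMCAG01","Ca7_30026017"
"CaMQAST7.5","CaLG07",44.84,43.555,46.125,5,"S7_15099099","S7_16104217"
"CaMQAST7.6","CaLG07",47.69,47.61,47.77,2,"S7_16381934","S7_16626703"
"CaMQAST7.7","CaLG07",58.07,56.305,59.835,35,"cpPb-682222","S7_20579963"
"CaMQAST7.8","CaLG07",71.07,68.945,73.195,11,"S7_23439225","S7_25218332"
"CaMQAST7.9","CaLG07",93.21,91.125,95.295,4,"ICCeM0033","CKAM1317"
"CaMQAST7.10","CaLG07",190.24,189.855,190.625,6,"S7_48148505","CNC_021166.1.34922231"
"CaMQAST8.1","CaLG08",5.24,4.695,5.785,18,"9385_8","9416_8"
"CaMQAST8.2","CaLG08",13.94,13.685,14.195,22,"S8_4717179","S8_4980923"
"CaMQAST8.3","CaLG08",22.83,21.31,24.35,4,"S8_7193960","S8_8293716"
"CaMQAST8.4","CaLG08",31.98,29.325,34.635,1,"TOG895142","S8_3639513"
"CaMQAST8.5","CaLG08",56.21,55.68,56.74,11,"ICCM0130a","S8_7118591"
"CaMQAST8.6","CaLG08",72.6,72.12,73.08,22,"CKaM1750","ICCeM054"
"CaMQAST8.7","CaLG08",82.44,82.4,82.48,22,"Ca8_4106644","Ca8_3050452"
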