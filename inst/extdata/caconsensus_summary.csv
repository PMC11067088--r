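"lg","n_markers","length_cm"
"CaLG01",1186,168.82
"CaLG02",858,139.64
"CaLG03",1138,331.1
"CaLG04",1954,392.7
"CaLG05",1276,142.795
"CaLG06",1550,372.26
"CaLG07",786,374.72
"CaLG08",529,144.71
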