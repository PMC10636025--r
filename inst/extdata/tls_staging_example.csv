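"id","stage_planar","stage_combined","contamination_flag"
"LS01","P-1","P-1",FALSE
"LS02","P-2","P-2",FALSE
"LS03","P-2","P-2",FALSE
"LS04","P-2","P-2",FALSE
"LS05","P-2","P-2",FALSE
"LS06","P-2","P-2",FALSE
"LS07","P-2","P-2",FALSE
"LS08","P-2","P-2",FALSE
"LS09","P-2","P-2",FALSE
"LS10","P-2","P-2",FALSE
"LS11","P-2","P-2",FALSE
"LS12","P-2","P-2",FALSE
"LS13","P-2","P-2",FALSE
"LS14","P-3","P-3",FALSE
"LS15","P-3","P-3",FALSE
"LS16","P-3","P-3",FALSE
"LS17","P-3","P-3",FALSE
"LS18","T-4","T-4",FALSE
"LS19","T-4","T-4",FALSE
"LS20","T-4","T-4",FALSE
"LS21","T-4","T-4",FALSE
"LS22","T-4","T-4",FALSE
"LS23","T-5","T-5",FALSE
"LS24","T-5","T-5",FALSE
"LS25","T-5","T-5",FALSE
"LS26","T-5","T-5",FALSE
"LS27","T-6","T-6",FALSE
"LS28","T-6","T-6",FALSE
"LS29","T-6","T-6",FALSE
"LS30","T-6","T-6",FALSE
"LS31","T-6","T-6",FALSE
"LS32","T-6","T-6",FALSE
"LS33","T-6","T-6",FALSE
"LS34","P-1","P-2",FALSE
"LS35","P-1","P-2",FALSE
"LS36","T-6","P-2",FALSE
"LS37","T-4","P-3",FALSE
"LS38","T-4","P-3",FALSE
"LS39","T-5","P-3",FALSE
"LS40","P-3","T-4",TRUE
"LS41","P-3","T-4",TRUE
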