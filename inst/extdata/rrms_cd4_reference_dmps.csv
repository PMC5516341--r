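probe_id,chrom,pos,dmr_index,gene,region_label,F_stat,p_value,p_truncated,mean_control,mean_case,delta_beta
cg17178900,1,205818956,1,PM20D1,Body,6.54,0.014,FALSE,0.470,0.646,0.176
cg26354017,1,205819088,1,PM20D1,1stExon,6.50,0.014,FALSE,0.411,0.599,0.188
cg14159672,1,205819179,1,PM20D1,1stExon,6.09,0.017,FALSE,0.444,0.616,0.173
cg14893161,1,205819251,1,PM20D1,5'UTR,7.42,0.009,FALSE,0.328,0.498,0.169
cg11965913,1,205819406,1,PM20D1,TSS200,5.38,0.025,FALSE,0.303,0.467,0.164
cg24503407,1,205819492,1,PM20D1,TSS1500,6.38,0.015,FALSE,0.404,0.560,0.157
cg25644740,6,29894152,2,HCG4P6,TSS1500,5.93,0.019,FALSE,0.448,0.612,0.164
cg04520169,6,29894195,2,HCG4P6,TSS1500,7.27,0.010,FALSE,0.377,0.524,0.148
cg23237314,6,29894197,2,HCG4P6,TSS1500,6.97,0.011,FALSE,0.374,0.492,0.117
cg08491487,6,30039130,3,RNF39,Body,10.02,0.003,FALSE,0.078,0.181,0.103
cg00947782,6,30039142,3,RNF39,Body,12.34,0.001,FALSE,0.102,0.210,0.108
cg03343571,6,30039175,3,RNF39,Body,13.64,0.001,FALSE,0.212,0.334,0.122
cg13185413,6,30039202,3,RNF39,Body,11.78,0.001,FALSE,0.206,0.326,0.119
cg09279736,6,30039403,3,RNF39,Body,14.19,0.0005,TRUE,0.287,0.404,0.117
cg07382347,6,30039408,3,RNF39,Body,13.22,0.001,FALSE,0.153,0.295,0.142
cg13401893,6,30039432,3,RNF39,Body,19.38,0.0005,TRUE,0.350,0.508,0.158
cg12633154,6,30039435,3,RNF39,Body,18.69,0.0005,TRUE,0.310,0.477,0.167
cg10568066,6,30039442,3,RNF39,Body,22.29,0.0005,TRUE,0.372,0.560,0.188
cg16078649,6,30039466,3,RNF39,Body,13.37,0.001,FALSE,0.346,0.451,0.105
cg10930308,6,30039476,3,RNF39,Body,12.69,0.001,FALSE,0.193,0.317,0.125
cg01341801,6,32489203,4,DRB5,Body,4.419,0.041,FALSE,0.249,0.455,0.205
cg26981746,6,32490012,4,DRB5,Body,4.645,0.036,FALSE,0.501,0.633,0.132
cg12015991,6,32490043,4,DRB5,Body,5.591,0.022,FALSE,0.649,0.778,0.128
cg08578320,6,32552039,5,DRB1,Body,6.558,0.014,FALSE,0.754,0.588,-0.166
cg09139047,6,32552042,5,DRB1,Body,5.129,0.028,FALSE,0.754,0.576,-0.179
cg15602423,6,32552095,5,DRB1,Body,8.966,0.004,FALSE,0.659,0.387,-0.272
cg15982117,6,32552106,5,DRB1,Body,5.811,0.020,FALSE,0.684,0.492,-0.192
cg14645244,6,32552205,5,DRB1,Body,6.068,0.017,FALSE,0.521,0.318,-0.203
cg09949906,6,32552350,5,DRB1,Body,5.076,0.029,FALSE,0.699,0.507,-0.192
cg10632894,6,32552453,5,DRB1,Body,4.536,0.038,FALSE,0.825,0.681,-0.144
cg01053087,8,637909,6,ERICH1,Body,10.55,0.002,FALSE,0.330,0.164,-0.166
cg05875700,8,638208,6,ERICH1,Body,8.864,0.005,FALSE,0.319,0.120,-0.199
cg12641240,8,638330,6,ERICH1,Body,6.055,0.018,FALSE,0.194,0.069,-0.125
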