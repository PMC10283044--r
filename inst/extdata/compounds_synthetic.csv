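id,name,class,n_cl,E,S,A,B,V,L,H_ref,T_ref,dU_aw,smiles,parent_id
PCB3,4-chlorobiphenyl (PCB 3),parent,1,1.480,1.050,0.000,0.220,1.4466,6.674,45,298.15,52000,,
PCB11,"3,3'-dichlorobiphenyl (PCB 11)",parent,2,1.600,1.110,0.000,0.180,1.5690,7.334,40,298.15,53000,,
PCB25,"2,3',4-trichlorobiphenyl (PCB 25)",parent,3,1.720,1.170,0.000,0.140,1.6914,7.994,35,298.15,54000,,
PCB28,"2,4,4'-trichlorobiphenyl (PCB 28)",parent,3,1.715,1.160,0.000,0.145,1.6914,7.960,33,298.15,54000,,
PCB52,"2,2',5,5'-tetrachlorobiphenyl (PCB 52)",parent,4,1.840,1.230,0.000,0.100,1.8138,8.654,28,298.15,55000,,
OH_PCB3,4-OH-PCB 3,hydroxylated,1,1.630,1.600,0.600,0.500,1.5641,7.374,,,,,PCB3
OH_PCB11,4-OH-PCB 11,hydroxylated,2,1.750,1.660,0.600,0.460,1.6865,8.034,,,,,PCB11
OH_PCB25,4-OH-PCB 25,hydroxylated,3,1.870,1.720,0.600,0.420,1.8089,8.694,,,,,PCB25
OH_PCB28,4-OH-PCB 28,hydroxylated,3,1.865,1.710,0.600,0.425,1.8089,8.660,,,,,PCB28
OH_PCB52,4-OH-PCB 52,hydroxylated,4,1.990,1.780,0.600,0.380,1.9313,9.354,,,,,PCB52
S_PCB3,4-OH-PCB 3 sulfate,sulfated,1,1.780,2.750,0.000,2.020,1.9136,8.674,,,,,PCB3
S_PCB11,4-OH-PCB 11 sulfate,sulfated,2,1.900,2.810,0.000,1.980,2.0360,9.334,,,,,PCB11
S_PCB25,4-OH-PCB 25 sulfate,sulfated,3,2.020,2.870,0.000,1.940,2.1584,9.994,,,,,PCB25
S_PCB28,4-OH-PCB 28 sulfate,sulfated,3,2.015,2.860,0.000,1.945,2.1584,9.960,,,,,PCB28
S_PCB52,4-OH-PCB 52 sulfate,sulfated,4,2.140,2.930,0.000,1.900,2.2808,10.654,,,,,PCB52
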