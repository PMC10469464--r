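name,class,chain_length,molar_mass,molar_volume_cm3_mol,melting_point_K,water_solubility_mol_m3,logD_NLW,logD_PLW,logD_ALBW,logD_SPW,logD_NLW_source,logD_PLW_source,logD_ALBW_source,logD_SPW_source
PFOA,PFCA,8,414.07,260,327,1.58,0.04,3.72,4.20,2.28,synthetic-measured,synthetic-measured,synthetic-measured,synthetic-measured
PFNA,PFCA,9,464.08,280,332,0.56,0.12,4.16,4.40,2.44,synthetic-measured,synthetic-measured,synthetic-measured,synthetic-measured
PFDA,PFCA,10,514.08,300,353,0.20,0.20,4.60,4.60,2.60,synthetic-measured,synthetic-measured,synthetic-measured,synthetic-measured
PFUdA,PFCA,11,564.09,320,368,0.070,0.28,5.04,4.80,2.76,synthetic-measured,synthetic-measured,synthetic-measured,synthetic-measured
PFDoA,PFCA,12,614.10,340,380,0.025,,,,,,,,
PFTrDA,PFCA,13,664.10,360,400,0.0089,,,,,,,,
PFTeDA,PFCA,14,714.11,380,430,0.0032,,,,,,,,
PFHxDA,PFCA,16,814.12,420,460,0.00040,,,,,,,,
PFBS,PFSA,4,300.10,190,300,20,-0.25,1.96,3.58,2.01,synthetic-measured,synthetic-measured,synthetic-measured,synthetic-measured
PFHxS,PFSA,6,400.11,230,350,3.0,-0.05,2.92,4.06,2.37,synthetic-measured,synthetic-measured,synthetic-measured,synthetic-measured
PFOS,PFSA,8,500.13,270,400,0.50,0.15,3.88,4.54,2.73,synthetic-measured,synthetic-measured,synthetic-measured,synthetic-measured
PFDS,PFSA,10,600.14,310,420,0.080,,,,,,,,
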