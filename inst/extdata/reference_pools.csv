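panel,organ,analyte,mean,se,unit
weights,liver,organ_weight,831,21,mg
weights,plasma,organ_weight,2151,26,mg
weights,lung,organ_weight,282,4,mg
weights,cerebrum,organ_weight,881,37,mg
weights,cerebellum,organ_weight,268,14,mg
water_soluble,liver,choline,194,13,nmol
water_soluble,liver,phosphocholine,98,8,nmol
water_soluble,liver,CDP-choline,1.0,0.2,nmol
water_soluble,liver,all_PC_precursors,293,19,nmol
water_soluble,liver,GPC,109,8,nmol
water_soluble,liver,betaine,1631,125,nmol
water_soluble,liver,DMG,39,2,nmol
water_soluble,liver,choline_derivatives,1657,125,nmol
water_soluble,liver,TMAO,1.0,0.3,nmol
water_soluble,liver,methionine,25,3,nmol
water_soluble,plasma,choline,75,7,nmol
water_soluble,plasma,phosphocholine,3.8,0.6,nmol
water_soluble,plasma,CDP-choline,0.4,0.1,nmol
water_soluble,plasma,all_PC_precursors,79,7,nmol
water_soluble,plasma,GPC,9,1,nmol
water_soluble,plasma,betaine,242,22,nmol
water_soluble,plasma,DMG,16,1,nmol
water_soluble,plasma,choline_derivatives,252,23,nmol
water_soluble,plasma,TMAO,3.0,0.8,nmol
water_soluble,plasma,methionine,4.4,0.3,nmol
water_soluble,lung,choline,92,12,nmol
water_soluble,lung,phosphocholine,29,2,nmol
water_soluble,lung,CDP-choline,0.2,0.03,nmol
water_soluble,lung,all_PC_precursors,122,13,nmol
water_soluble,lung,GPC,34,2,nmol
water_soluble,lung,betaine,29,2,nmol
water_soluble,lung,DMG,2.6,0.2,nmol
water_soluble,lung,choline_derivatives,30,2,nmol
water_soluble,lung,TMAO,1.6,0.4,nmol
water_soluble,lung,methionine,3.8,0.5,nmol
water_soluble,cerebrum,choline,230,17,nmol
water_soluble,cerebrum,phosphocholine,375,31,nmol
water_soluble,cerebrum,CDP-choline,16,2,nmol
water_soluble,cerebrum,all_PC_precursors,621,45,nmol
water_soluble,cerebrum,GPC,55,13,nmol
water_soluble,cerebrum,betaine,21,2,nmol
water_soluble,cerebrum,DMG,7.7,0.6,nmol
water_soluble,cerebrum,choline_derivatives,26,2,nmol
water_soluble,cerebrum,TMAO,0.31,0.07,nmol
water_soluble,cerebrum,methionine,24.6,4.1,nmol
water_soluble,cerebellum,choline,193,29,nmol
water_soluble,cerebellum,phosphocholine,329,36,nmol
water_soluble,cerebellum,CDP-choline,13,1,nmol
water_soluble,cerebellum,all_PC_precursors,533,63,nmol
water_soluble,cerebellum,GPC,36,7,nmol
water_soluble,cerebellum,betaine,15,2,nmol
water_soluble,cerebellum,DMG,6.5,0.9,nmol
water_soluble,cerebellum,choline_derivatives,20,2,nmol
water_soluble,cerebellum,TMAO,0.22,0.03,nmol
water_soluble,cerebellum,methionine,19.2,4.9,nmol
lipid,liver,PC,19.9,1.0,umol
lipid,liver,lysoPC,0.19,0.010,umol
lipid,liver,SPH,2.71,0.10,umol
lipid,liver,choline_phospholipids,22.8,1.0,umol
lipid,plasma,PC,4.7,0.2,umol
lipid,plasma,lysoPC,0.44,0.03,umol
lipid,plasma,SPH,0.39,0.02,umol
lipid,plasma,choline_phospholipids,5.5,0.2,umol
lipid,lung,PC,5.6,0.3,umol
lipid,lung,lysoPC,0.052,0.004,umol
lipid,lung,SPH,1.0,0.1,umol
lipid,lung,choline_phospholipids,6.7,0.3,umol
lipid,LLF,PC,0.50,0.04,umol
lipid,LLF,lysoPC,0.002,0.001,umol
lipid,LLF,SPH,0.01,0.005,umol
lipid,LLF,choline_phospholipids,0.51,0.05,umol
lipid,cerebrum,PC,19.0,1.6,umol
lipid,cerebrum,lysoPC,0.063,0.007,umol
lipid,cerebrum,SPH,0.87,0.09,umol
lipid,cerebrum,choline_phospholipids,20.0,1.7,umol
lipid,cerebellum,PC,5.4,0.6,umol
lipid,cerebellum,lysoPC,0.019,0.003,umol
lipid,cerebellum,SPH,0.35,0.03,umol
lipid,cerebellum,choline_phospholipids,5.8,0.6,umol
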