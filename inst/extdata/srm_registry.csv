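name,class,label_state,precursor_mz,product_mz,n_carbons,n_labeled_methyls,internal_standard,acyl_group
choline,water_soluble,unlabeled,104,60,5,0,D4-choline,n/a
D3-choline,water_soluble,D3,107,63,5,1,D4-choline,n/a
D4-choline,water_soluble,D4_IS,108,60,5,0,,n/a
D4-choline-m61,water_soluble,D4_IS,108,61,5,0,,n/a
D9-choline,water_soluble,D9,113,69,5,3,D4-choline,n/a
betaine,water_soluble,unlabeled,118,59,5,0,D4-choline,n/a
D9-betaine,water_soluble,D9,127,68,5,3,D4-choline,n/a
phosphocholine,water_soluble,unlabeled,184,86,5,0,D4-choline,n/a
D9-phosphocholine,water_soluble,D9,193,95,5,3,D4-choline,n/a
DMG,water_soluble,unlabeled,104,58,4,0,D4-choline,n/a
D6-DMG,water_soluble,D6,110,64,4,2,D4-choline,n/a
GPC,water_soluble,unlabeled,258,104,8,0,D4-choline,n/a
D9-GPC,water_soluble,D9,267,113,8,3,D4-choline,n/a
methionine,water_soluble,unlabeled,150,61,5,0,D4-choline,n/a
D3-methionine,water_soluble,D3,153,64,5,1,D4-choline,n/a
carnitine,water_soluble,unlabeled,162,60,7,0,D4-choline,n/a
D3-carnitine,water_soluble,D3,165,63,7,1,D4-choline,n/a
PC16:0/16:0,PC,unlabeled,734.6,184.1,40,0,PC20:0/20:0,sat
PC16:0/18:2,PC,unlabeled,758.6,184.1,42,0,PC20:0/20:0,C18:2
PC16:0/18:1,PC,unlabeled,760.6,184.1,42,0,PC20:0/20:0,C18:1
PC16:0/20:4,PC,unlabeled,782.6,184.1,44,0,PC20:0/20:0,C20:4
PC18:0/18:2,PC,unlabeled,786.6,184.1,44,0,PC20:0/20:0,C18:2
PC18:0/18:1,PC,unlabeled,788.6,184.1,44,0,PC20:0/20:0,C18:1
PC16:0/22:6,PC,unlabeled,806.6,184.1,46,0,PC20:0/20:0,C22:6
PC18:0/20:4,PC,unlabeled,810.6,184.1,46,0,PC20:0/20:0,C20:4
PC18:0/22:6,PC,unlabeled,834.7,184.1,48,0,PC20:0/20:0,C22:6
PC20:0/20:0,PC,unlabeled,846.7,184.1,48,0,,sat
D9-PC16:0/16:0,PC,D9,743.7,193.1,40,3,PC20:0/20:0,sat
D9-PC16:0/18:2,PC,D9,767.7,193.1,42,3,PC20:0/20:0,C18:2
D9-PC16:0/18:1,PC,D9,769.7,193.1,42,3,PC20:0/20:0,C18:1
D9-PC16:0/20:4,PC,D9,791.7,193.1,44,3,PC20:0/20:0,C20:4
D9-PC18:0/18:2,PC,D9,795.7,193.1,44,3,PC20:0/20:0,C18:2
D9-PC18:0/18:1,PC,D9,797.7,193.1,44,3,PC20:0/20:0,C18:1
D9-PC16:0/22:6,PC,D9,815.7,193.1,46,3,PC20:0/20:0,C22:6
D9-PC18:0/20:4,PC,D9,819.7,193.1,46,3,PC20:0/20:0,C20:4
D9-PC18:0/22:6,PC,D9,843.7,193.1,48,3,PC20:0/20:0,C22:6
D3-PC16:0/16:0,PC,D3,737.6,187.1,40,1,PC20:0/20:0,sat
D3-PC16:0/18:2,PC,D3,761.6,187.1,42,1,PC20:0/20:0,C18:2
D3-PC16:0/18:1,PC,D3,763.6,187.1,42,1,PC20:0/20:0,C18:1
D3-PC16:0/20:4,PC,D3,785.6,187.1,44,1,PC20:0/20:0,C20:4
D3-PC18:0/18:2,PC,D3,789.6,187.1,44,1,PC20:0/20:0,C18:2
D3-PC18:0/18:1,PC,D3,791.6,187.1,44,1,PC20:0/20:0,C18:1
D3-PC16:0/22:6,PC,D3,809.6,187.1,46,1,PC20:0/20:0,C22:6
D3-PC18:0/20:4,PC,D3,813.6,187.1,46,1,PC20:0/20:0,C20:4
D3-PC18:0/22:6,PC,D3,837.7,187.1,48,1,PC20:0/20:0,C22:6
lysoPC16:0,lysoPC,unlabeled,496.3,184.1,24,0,PC20:0/20:0,n/a
D9-lysoPC16:0,lysoPC,D9,505.4,193.1,24,3,PC20:0/20:0,n/a
D3-lysoPC16:0,lysoPC,D3,499.4,187.1,24,1,PC20:0/20:0,n/a
SPH16:0,SPH,unlabeled,703.6,184.1,39,0,PC20:0/20:0,n/a
D9-SPH16:0,SPH,D9,712.6,193.1,39,3,PC20:0/20:0,n/a
D3-SPH16:0,SPH,D3,706.6,187.1,39,1,PC20:0/20:0,n/a
PE14:0/14:0,PE,unlabeled,636.5,495.5,33,0,,sat
PE16:0/18:2,PE,unlabeled,716.5,575.5,39,0,PE14:0/14:0,C18:2
PE18:0/18:1,PE,unlabeled,746.6,605.6,41,0,PE14:0/14:0,C18:1
PE16:0/20:4,PE,unlabeled,740.5,599.5,41,0,PE14:0/14:0,C20:4
PE18:0/22:6,PE,unlabeled,792.6,651.6,45,0,PE14:0/14:0,C22:6
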