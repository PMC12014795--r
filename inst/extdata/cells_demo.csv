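area_id,cell_id,level
P01_A1,1,0
P01_A1,2,1
P01_A1,3,1
P01_A1,4,2
P01_A1,5,3
P01_A2,1,2
P01_A2,2,2
P01_A2,3,3
P01_A2,4,3
P01_A2,5,3
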