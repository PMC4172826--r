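condition,count_ap,count_ly,count_al,size_ap,size_ly,size_al,provenance
FM,31,19,28,0.08,0.10,0.30,synthetic placeholder - replace with measured vesicle statistics
FM_BAF,25,30,45,0.08,0.13,0.40,synthetic placeholder - replace with measured vesicle statistics
ND,46,38,32,0.08,0.10,0.30,synthetic placeholder - replace with measured vesicle statistics
ND_BAF,40,45,50,0.08,0.13,0.40,synthetic placeholder - replace with measured vesicle statistics
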