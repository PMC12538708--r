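class_label,true_count,detected_count,mass_g
soybean,1954,1919,500
a_artemisiifolia,105,100,5
a_trifida,97,93,5
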