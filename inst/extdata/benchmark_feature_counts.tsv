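dataset	n_features	n_selected
thyroid	28	5
solar_flare	10	3
scene	294	8
music	71	6
yeast	103	7
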