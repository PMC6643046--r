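sample	replicate	n_native	n_denatured
Halo-eYFP-ZnF 1-11	1	0.258	0.990
Halo-eYFP-ZnF 1-11	2	0.242	0.829
Halo-eYFP-ZnF 1-11	3	0.295	0.988
Halo-eYFP-ZnF 1-11	4	0.419	1.237
Halo-eYFP-ZnF 1-11	5	0.356	1.123
eYFP	1	0.228	0.336
eYFP	2	0.235	0.289
eYFP	3	0.229	0.404
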