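group	condition	overlapping	total
responding	myoblast	12	43
responding	myotube	25	43
non_responding	myoblast	23	199
non_responding	myotube	31	199
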