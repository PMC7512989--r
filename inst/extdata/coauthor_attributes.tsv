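node	topic	country
David	ML	US
Jia	DM	CN
Jones	DM	US
George	DM	AU
Ying	DM	CN
Hua	ML	CN
Pitt	DM	AU
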