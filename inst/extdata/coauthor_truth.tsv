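node	community
David	C1
Jia	C1
Jones	C1
George	C2
Ying	C2
Hua	C2
Pitt	C2
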