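David	Jia
David	Jones
Jia	Jones
Jones	George
George	Ying
Ying	Hua
Ying	Pitt
Hua	Pitt
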