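sample	compartment
TH	TH
THC	THC
PC	PC
P	P
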