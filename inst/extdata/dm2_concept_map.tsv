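diabetes mellitus type 2	C0011860
diabetes mellitus type II	C0011860
type two diabetes mellitus	C0011860
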