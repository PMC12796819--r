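human_symbol	mouse_symbol
CYP4A11	Cyp4a10
CYP4A11	Cyp4a14
ACOT1	Acot1
ACOT2	Acot2
HMGCS1	Hmgcs1
HMGCS2	Hmgcs2
EHHADH	Ehhadh
PKLR	Pklr
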