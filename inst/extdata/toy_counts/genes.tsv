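ADCY1	ADCY1
ADCY2	ADCY2
ADCY3	ADCY3
ADCY4	ADCY4
ADCY5	ADCY5
ADCY6	ADCY6
ADCY7	ADCY7
ADCY8	ADCY8
ADCY9	ADCY9
ADCY10	ADCY10
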