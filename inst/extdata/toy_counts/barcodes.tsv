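cell000001
cell000002
cell000003
cell000004
cell000005
cell000006
cell000007
cell000008
cell000009
cell000010
cell000011
cell000012
cell000013
cell000014
cell000015
cell000016
cell000017
cell000018
cell000019
cell000020
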