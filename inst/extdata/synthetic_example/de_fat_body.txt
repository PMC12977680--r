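g00002
g00005
g00008
g00011
g00014
g00017
g00020
g00023
g00026
g00029
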