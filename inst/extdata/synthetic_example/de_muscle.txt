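g00003
g00006
g00009
g00012
g00015
g00018
g00021
g00024
g00027
g00030
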