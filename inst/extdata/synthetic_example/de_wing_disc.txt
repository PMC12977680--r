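g00001
g00004
g00007
g00010
g00013
g00016
g00019
g00022
g00025
g00028
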