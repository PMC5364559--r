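>v1
ACDE
>bad1
ACXE
>v2
MKLV
>v3
WYHH
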