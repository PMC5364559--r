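>p1
ACDE
>p2 some description
acdefghiklmnpqrstvwy
ACDEFGHIKLMNPQRSTVWY
>p3
MKLV
>p4
GGGGGGGGGG
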