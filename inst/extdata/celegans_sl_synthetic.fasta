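>SL1
GGTTTAATTACCCAAGTTTGAG
>SL2
GGTTTTAACCCAGTTACTCAAG
>SL3
GGTTTTAACCCAGTTAACCAAG
>SL4
GGTTTTAACCCAGTTTAACCAAG
>SL5
GGTTTTAACCCAGTTACCAAG
>SL6
GGTTTAAAACCCAGTTACCAAG
>SL7
GGTTTTAACCCAGTTAATTGAG
>SL8
GGTTTTTACCCAGTTAACCAAG
>SL9
GGTTTATACCCAGTTAACCAAG
>SL10
GGTTTTAACCCAAGTTAACCAAG
>SL11
GGTTTTAACCAGTTAACTAAG
>SL12
GGTTTTAACCCATATAACCAAG
>SL13
GGTTTTAACCCATTTAACCAAG
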