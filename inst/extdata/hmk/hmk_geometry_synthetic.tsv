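type	mass	radius
H4	11.4	13.69
H2A	14	14.66
H2B	13.8	14.59
Ska1	29.5	18.79
Ska2	14	14.66
Ska3	46	21.79
MT	110	29.14
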