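type	mass	radius
CenpA	16	15.33
CenpB	65	24.46
CenpC	107	28.88
CenpI	87	26.95
CenpK	31.5	19.21
CenpM	20	16.51
CenpN	39.5	20.71
CenpO	34	19
CenpP	33	19.51
CenpQ	30.5	19.01
CenpR	20	16.51
CenpS	16	15.33
CenpT	60.5	23.88
CenpU	47.5	22.03
CenpW	10	13.1
CenpX	9	12.65
H3	15	15
Dsn1	40	20.8
Mis12	24	17.55
Nnf1	23.5	17.42
Nsl1	32	19.31
Hec1	74	25.54
Nuf2	54	22.99
Spc24	22.5	17.17
Spc25	26	18.02
Knl1	265	39.07
Apc1	216.5	36.53
Apc2	94	27.66
Apc3	92	27.46
Apc4	92	27.46
Apc5	85	26.75
Apc6	71.5	25.25
Apc7	67	24.71
Apc8	69	24.95
Apc10	21	16.78
Apc11	10	13.11
Apc12	10	13.11
Apc13	8.5	12.41
Cdc20	55	23.13
Mad1	83	26.53
Mad2	23.5	17.42
Bub1	122	30.17
BubR1	120	30
Bub3	37	20.27
Mps1	97	27.95
Zwint	31	19.11
Zwilch	67	24.71
Zw10	89	27.16
Rod1	250	38.32
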