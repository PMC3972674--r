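protein_a	protein_b	site_a	site_b	rate_tag	switch_tag
CenpA	CenpB	cenpb	cenpa		
CenpA	CenpN	cenpn	cenpa		
CenpA	CenpC	cenpc	cenpa		
CenpB	CenpW	cenpw	cenpb		
CenpB	CenpQ	cenpq	cenpb		
CenpB	CenpU	cenpu	cenpb		
CenpB	CenpC	cenpc	cenpb		
CenpI	CenpU	cenpu	cenpi		
CenpK	CenpO	cenpo	cenpk		
CenpK	CenpR	cenpr	cenpk		
CenpK	CenpU	cenpu	cenpk		
CenpK	CenpN	cenpn	cenpk		
CenpM	CenpS	cenps	cenpm		
CenpM	CenpU	cenpu	cenpm		
CenpM	CenpT	cenpt	cenpm		
CenpM	H3	h3	cenpm		
CenpO	CenpP	cenpp	cenpo		
CenpO	CenpU	cenpu	cenpo		
CenpO	CenpQ	cenpq	cenpo		
CenpP	CenpU	cenpu	cenpp		
CenpP	CenpQ	cenpq	cenpp		
CenpQ	CenpU	cenpu	cenpq		
CenpR	CenpU	cenpu	cenpr		
CenpS	H3	h3	cenps		
CenpS	CenpT	cenpt	cenps		
CenpS	CenpX	cenpx	cenps		
CenpT	H3	h3	cenpt		
CenpW	H3	h3	cenpw		
Dsn1	Mis12	mis12	dsn1		
Dsn1	Nsl1	nsl1	dsn1		
Nnf1	Mis12	mis12	nnf1		
Nnf1	CenpC	cenpc	nnf1		
Nsl1	Spc24	spc24	nsl1		
Nsl1	Spc25	spc25	nsl1		
Hec1	Nuf2	nuf2	hec1		
Nuf2	Spc25	spc25	nuf2		
Spc24	Spc25	spc25	spc24		
Spc24	CenpT	cenpt	spc24		
Cdc20	Mad2	mad2	cdc20		SAC
Cdc20	BubR1	bubr1	cdc20		SAC
Cdc20	Apc2	apc2	cdc20		SAC
Mad2	Mad1	mad1	mad2		SAC
Mad2	Rod1	rod1	mad2		SAC
Mad2	Zw10	zw10	mad2		SAC
Mad1	Bub1	bub1	mad1		SAC
Mad1	Rod1	rod1	mad1		SAC
Mad1	Zw10	zw10	mad1		SAC
Bub3	Bub1	bub1	bub3		SAC
Bub3	BubR1	bubr1	bub3		SAC
BubR1	Bub1	bub1	bubr1		SAC
BubR1	Knl1	knl1	bubr1		
BubR1	Apc3	apc3	bubr1		SAC
BubR1	Apc4	apc4	bubr1		SAC
BubR1	Apc5	apc5	bubr1		SAC
BubR1	Mps1	mps1	bubr1		SAC
BubR1	Rod1	rod1	bubr1		SAC
BubR1	Zw10	zw10	bubr1		SAC
Bub1	Knl1	knl1	bub1		
Mps1	Mis12	mis12	mps1		
Mps1	Hec1	hec1	mps1		
Zwint	Zw10	zw10	zwint		SAC
Zwint	Knl1	knl1	zwint		
Zwint	Mis12	mis12	zwint		
Zwilch	Rod1	rod1	zwilch		SAC
Zwilch	Zw10	zw10	zwilch		SAC
Zw10	Rod1	rod1	zw10		SAC
Zw10	Knl1	knl1	zw10		
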