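template	member	type	x	y	z	rigid	fixed	rot_free	active
NucCenpA	1	CenpA	20	0	12	TRUE	TRUE	TRUE	TRUE
NucCenpA	2	H4	1.22464679914735e-15	20	12	TRUE	TRUE	TRUE	TRUE
NucCenpA	3	CenpA	-20	2.44929359829471e-15	12	TRUE	TRUE	TRUE	FALSE
NucCenpA	4	H4	-3.67394039744206e-15	-20	12	TRUE	TRUE	TRUE	TRUE
NucCenpA	5	H2A	14.142135623731	14.1421356237309	-12	TRUE	TRUE	TRUE	TRUE
NucCenpA	6	H2B	-14.1421356237309	14.142135623731	-12	TRUE	TRUE	TRUE	TRUE
NucCenpA	7	H2A	-14.142135623731	-14.1421356237309	-12	TRUE	TRUE	TRUE	TRUE
NucCenpA	8	H2B	14.1421356237309	-14.142135623731	-12	TRUE	TRUE	TRUE	TRUE
NucH3	1	H3	20	0	12	TRUE	TRUE	TRUE	TRUE
NucH3	2	H4	1.22464679914735e-15	20	12	TRUE	TRUE	TRUE	TRUE
NucH3	3	H3	-20	2.44929359829471e-15	12	TRUE	TRUE	TRUE	TRUE
NucH3	4	H4	-3.67394039744206e-15	-20	12	TRUE	TRUE	TRUE	TRUE
NucH3	5	H2A	14.142135623731	14.1421356237309	-12	TRUE	TRUE	TRUE	TRUE
NucH3	6	H2B	-14.1421356237309	14.142135623731	-12	TRUE	TRUE	TRUE	TRUE
NucH3	7	H2A	-14.142135623731	-14.1421356237309	-12	TRUE	TRUE	TRUE	TRUE
NucH3	8	H2B	14.1421356237309	-14.142135623731	-12	TRUE	TRUE	TRUE	TRUE
Mis12C	1	Nnf1	-55.43	0	0	FALSE	FALSE	FALSE	TRUE
Mis12C	2	Mis12	-20.46	0	0	FALSE	FALSE	FALSE	TRUE
Mis12C	3	Dsn1	17.89	0	0	FALSE	FALSE	FALSE	TRUE
Mis12C	4	Nsl1	58	0	0	FALSE	FALSE	FALSE	TRUE
Ndc80C	1	Spc24	-59.03	0	0	FALSE	FALSE	FALSE	TRUE
Ndc80C	2	Spc25	-23.84	0	0	FALSE	FALSE	FALSE	TRUE
Ndc80C	3	Nuf2	17.17	0	0	FALSE	FALSE	FALSE	TRUE
Ndc80C	4	Hec1	65.7	0	0	FALSE	FALSE	FALSE	TRUE
MadMad2	1	Mad1	-21.975	0	0	FALSE	FALSE	FALSE	TRUE
MadMad2	2	Mad2	21.975	0	0	FALSE	FALSE	FALSE	TRUE
RZZ	1	Rod1	-60.9433333333333	0	0	FALSE	FALSE	FALSE	TRUE
RZZ	2	Zw10	4.53666666666667	0	0	FALSE	FALSE	FALSE	TRUE
RZZ	3	Zwilch	56.4066666666667	0	0	FALSE	FALSE	FALSE	TRUE
APC	1	Apc1	-285.988333333333	0	0	FALSE	FALSE	FALSE	TRUE
APC	2	Apc2	-221.798333333333	0	0	FALSE	FALSE	FALSE	TRUE
APC	3	Apc3	-166.678333333333	0	0	FALSE	FALSE	FALSE	TRUE
APC	4	Apc4	-111.758333333333	0	0	FALSE	FALSE	FALSE	TRUE
APC	5	Apc5	-57.5483333333333	0	0	FALSE	FALSE	FALSE	TRUE
APC	6	Apc6	-5.54833333333329	0	0	FALSE	FALSE	FALSE	TRUE
APC	7	Apc7	44.4116666666667	0	0	FALSE	FALSE	FALSE	TRUE
APC	8	Apc8	94.0716666666667	0	0	FALSE	FALSE	FALSE	TRUE
APC	9	Apc10	135.801666666667	0	0	FALSE	FALSE	FALSE	TRUE
APC	10	Apc11	165.691666666667	0	0	FALSE	FALSE	FALSE	TRUE
APC	11	Apc12	191.911666666667	0	0	FALSE	FALSE	FALSE	TRUE
APC	12	Apc13	217.431666666667	0	0	FALSE	FALSE	FALSE	TRUE
Ska	1	Ska3	-88.69	0	-12.5	FALSE	FALSE	FALSE	TRUE
Ska	2	Ska2	-52.24	0	12.5	FALSE	FALSE	FALSE	TRUE
Ska	3	Ska1	-18.79	0	-12.5	FALSE	FALSE	FALSE	TRUE
Ska	4	Ska1	18.79	0	12.5	FALSE	FALSE	FALSE	TRUE
Ska	5	Ska2	52.24	0	-12.5	FALSE	FALSE	FALSE	TRUE
Ska	6	Ska3	88.69	0	12.5	FALSE	FALSE	FALSE	TRUE
MT	1	MT	95.86	0	-58.28	TRUE	TRUE	FALSE	TRUE
MT	2	MT	67.7832560445425	67.7832560445424	-58.28	TRUE	TRUE	FALSE	TRUE
MT	3	MT	5.86973210831326e-15	95.86	-58.28	TRUE	TRUE	FALSE	TRUE
MT	4	MT	-67.7832560445424	67.7832560445425	-58.28	TRUE	TRUE	FALSE	TRUE
MT	5	MT	-95.86	1.17394642166265e-14	-58.28	TRUE	TRUE	FALSE	TRUE
MT	6	MT	-67.7832560445425	-67.7832560445424	-58.28	TRUE	TRUE	FALSE	TRUE
MT	7	MT	-1.76091963249398e-14	-95.86	-58.28	TRUE	TRUE	FALSE	TRUE
MT	8	MT	67.7832560445424	-67.7832560445425	-58.28	TRUE	TRUE	FALSE	TRUE
MT	9	MT	95.86	0	0	TRUE	TRUE	FALSE	TRUE
MT	10	MT	67.7832560445425	67.7832560445424	0	TRUE	TRUE	FALSE	TRUE
MT	11	MT	5.86973210831326e-15	95.86	0	TRUE	TRUE	FALSE	TRUE
MT	12	MT	-67.7832560445424	67.7832560445425	0	TRUE	TRUE	FALSE	TRUE
MT	13	MT	-95.86	1.17394642166265e-14	0	TRUE	TRUE	FALSE	TRUE
MT	14	MT	-67.7832560445425	-67.7832560445424	0	TRUE	TRUE	FALSE	TRUE
MT	15	MT	-1.76091963249398e-14	-95.86	0	TRUE	TRUE	FALSE	TRUE
MT	16	MT	67.7832560445424	-67.7832560445425	0	TRUE	TRUE	FALSE	TRUE
MT	17	MT	95.86	0	58.28	TRUE	TRUE	FALSE	TRUE
MT	18	MT	67.7832560445425	67.7832560445424	58.28	TRUE	TRUE	FALSE	TRUE
MT	19	MT	5.86973210831326e-15	95.86	58.28	TRUE	TRUE	FALSE	TRUE
MT	20	MT	-67.7832560445424	67.7832560445425	58.28	TRUE	TRUE	FALSE	TRUE
MT	21	MT	-95.86	1.17394642166265e-14	58.28	TRUE	TRUE	FALSE	TRUE
MT	22	MT	-67.7832560445425	-67.7832560445424	58.28	TRUE	TRUE	FALSE	TRUE
MT	23	MT	-1.76091963249398e-14	-95.86	58.28	TRUE	TRUE	FALSE	TRUE
MT	24	MT	67.7832560445424	-67.7832560445425	58.28	TRUE	TRUE	FALSE	TRUE
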