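protein_id	length	locations	evidence	reviewed	glycosylated	structures
P01	300	nuclear		yes	no	1aaa:250
P02	400	nuclear,cytoplasmic		yes	no	1bbb:300,2bbb:100
P03	322	cytoplasmic		yes	no	1ccc:200
P04	250	extracellular		yes	no	1ddd:240
P05	149	nuclear		yes	no	1eee:149
P06	500	extracellular		yes	yes	1fff:400
P07	310	nuclear	by similarity	yes	no	1ggg:300
P08	280	cytoplasmic		no	no	1hhh:200
P09	330	nuclear,membrane		yes	no	1iii:300
P10	260	mitochondrion		yes	no	1jjj:200
P11	340	nuclear		yes	no
P12	290	cytoplasmic	probable	yes	no	1kkk:250
P13	150	extracellular		yes	no	1lll:150
P14	360	nucleus		yes	no	1mmm:300
P15	270	cytosol		yes	no	1nnn:180
P16	420	nuclear,cytoplasm		yes	yes	1ooo:350
P17	230	extracellular	potential	yes	no	1ppp:200
P18	1000	nuclear		yes	no	1qqq:500,2qqq:800
P19	200			yes	no	1rrr:150
P20	120	cytoplasmic		yes	no	1sss:100
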