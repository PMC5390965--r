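canonical_string	count	K_bits
0	2000	0.605968358841458
00	508	2.58306795673138
000	4	9.57175264350355
0000	2	10.5717526435035
001	6	8.98679014278239
0010	2	10.5717526435035
01	508	2.58306795673138
010	4	9.57175264350355
0100	2	10.5717526435035
011	6	8.98679014278239
0110	2	10.5717526435035
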