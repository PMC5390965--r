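canonical_string	count	K_bits
0	11664	0.600708305489289
0/0	1484	3.57520793319542
0/0/0	4	12.1104833098162
0/0/0/0	2	13.1104833098162
0/0/1	6	11.5255208090951
0/0/1/0	2	13.1104833098162
0/1	1484	3.57520793319542
0/1/0	4	12.1104833098162
0/1/0/0	2	13.1104833098162
0/1/1	6	11.5255208090951
0/1/1/0	2	13.1104833098162
00	1484	3.57520793319542
000	4	12.1104833098162
0000	2	13.1104833098162
001	6	11.5255208090951
001/100	4	12.1104833098162
001/110	4	12.1104833098162
0010	2	13.1104833098162
01	1484	3.57520793319542
01/00/10	4	12.1104833098162
01/01/10	4	12.1104833098162
01/10/10	4	12.1104833098162
01/11/10	4	12.1104833098162
010	4	12.1104833098162
0100	2	13.1104833098162
011	6	11.5255208090951
011/100	4	12.1104833098162
011/110	4	12.1104833098162
0110	2	13.1104833098162
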