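time_weeks,value,quantity
0,9.3,strength_N
1,6.9,strength_N
2,5.3,strength_N
3,2.1,strength_N
4,1.2,strength_N
6,0.4,strength_N
9,0.1,strength_N
0,194267,mw_da
1,163566,mw_da
2,124383,mw_da
4,82709,mw_da
6,51737,mw_da
8,32867,mw_da
13,8655,mw_da
20,6190,mw_da
25,4387,mw_da
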