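genotype,haplotype,comp140766_c3_seq1_A,comp140766_c3_seq1_B,comp141987_c0_seq1_A,comp141987_c0_seq1_B,comp144295_c3_seq1_A,comp144295_c3_seq1_B,comp152737_c0_seq2_A,comp152737_c0_seq2_B,comp152973_c0_seq1_A,comp152973_c0_seq1_B,comp162701_c0_seq4_A,comp162701_c0_seq4_B,comp163630_c0_seq1_A,comp163630_c0_seq1_B,comp132525_c0_seq1_A,comp132525_c0_seq1_B,comp141103_c0_seq2_A,comp141103_c0_seq2_B,comp146583_c0_seq2_A,comp146583_c0_seq2_B,ss804270605_A,ss804270605_B,ss804270596_A,ss804270596_B,ss804270598_A,ss804270598_B,ss804270584_A,ss804270584_B,ss804270595_A,ss804270595_B,ss804270614_A,ss804270614_B
1,t/22,C,C,T,C,T,A,A,A,G,G,T,C,T,C,C,A,T,T,G,G,G,A,A,A,C,C,T,C,T,C,T,C
2,t/22,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,G,.,.,.,.,.,.,.,.,.,.
3,t/22,.,.,.,T,.,T,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.
4,t/22,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,C,.,.,.,.,.
5,t/22,.,.,.,.,.,.,.,.,.,.,.,T,.,.,.,.,.,.,.,.,.,.,.,.,.,.,C,.,.,.,.,.
6,t/22,.,.,.,.,.,.,G,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,C,.,.,.,.,.
7,t/22,.,.,.,.,.,T,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,T
8,t/22,.,.,.,T,?,?,.,.,.,.,.,T,C,.,.,C,.,.,.,.,.,.,.,.,.,.,.,T,.,T,?,?
9,z2/37,T,T,C,.,A,.,G,G,.,A,C,.,.,T,A,.,C,C,.,C,A,.,G,.,T,T,C,.,C,.,.,T
10,z2/37,T,T,C,.,?,?,G,G,A,A,C,.,.,T,A,.,C,C,C,C,A,.,G,G,T,T,C,.,C,.,?,?
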