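inclusion_order,locus,linkage_group,DP,n_alleles,effective_alleles,n_patterns,cumulative_genotypes
1,CH01d09,12,0.973,19,9.8,78,78
2,CH-Vf1,1,0.968,14,7.3,51,126
3,CH02b10,2,0.966,22,7.6,62,135
4,CH01f07,10,0.965,23,7.9,64,137
5,NB109,3,0.965,26,7.2,69,140
6,CH01d03,4,0.963,17,7.1,56,142
7,GD142,9,0.961,22,7.7,61,143
8,EMPc11,11,0.950,12,5.1,45,143
9,NB103,5,0.949,17,6.0,56,144
10,CH02d11,15,0.944,16,5.1,44,144
11,EMPc117,7,0.937,18,4.8,51,144
12,CH05c06,16,0.922,13,3.9,31,144
13,CH03d12,6,0.918,13,4.3,31,144
14,CH01h10,8,0.913,13,3.7,36,144
15,GD147,13,0.848,13,2.7,34,145
16,NB105,11,0.948,14,5.9,46,145
17,NH029,9,0.947,12,6.1,44,145
18,CH02c11,10,0.946,17,4.9,48,145
19,CH01d08,15,0.943,10,5.2,39,146
20,CH03g07,3,0.943,22,6.8,59,146
21,NZ05g08,4,0.942,10,5.4,41,149
22,NB106,9,0.877,17,4.0,47,151
23,NH023,3,0.876,18,2.9,27,153
24,CH02c09,15,0.874,12,2.5,33,155
25,CH04e03,5,0.566,9,1.7,12,155
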