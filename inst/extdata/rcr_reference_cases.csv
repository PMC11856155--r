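case,outlet,Rd,Rp,C
CASE1,BCA,5.62e8,5.08e7,2.42e-9
CASE1,LCCA,1.44e9,1.31e8,9.42e-10
CASE1,LSA,1.37e9,1.24e8,9.96e-10
CASE1,DA,2.51e8,2.28e7,5.41e-9
CASE2,BCA,8.81e8,7.98e7,1.54e-9
CASE2,LCCA,3.39e9,3.07e8,4.02e-10
CASE2,LSA,1.06e9,9.62e7,1.28e-9
CASE2,DA,2.08e8,1.88e7,6.55e-9
CASE3,BCA,8.87e8,8.03e7,2.06e-9
CASE3,LCCA,3.61e9,3.27e8,3.77e-10
CASE3,LSA,1.29e9,1.16e8,1.06e-9
CASE3,DA,2.00e8,1.81e7,6.80e-9
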