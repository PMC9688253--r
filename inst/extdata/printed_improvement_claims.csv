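classifier,dataset,strategy,set,claimed_pp,source
DT,HAM 10000,MOWFS-AJS,ranked,3.14,results-text
DT,HAM 10000,FOWFS-AJS,ranked,3.12,results-text
DT,BCN 20000,MOWFS-AJS,ranked,7.77,results-text
DT,BCN 20000,FOWFS-AJS,ranked,7.75,results-text
DT,HAM 10000,MOWFS-AJS,fused,1.09,figure-text
DT,HAM 10000,MOWFS-AJS,ranked,2.91,figure-text
DT,BCN 20000,MOWFS-AJS,fused,3.51,figure-text
DT,BCN 20000,MOWFS-AJS,ranked,7.75,figure-text
NB,HAM 10000,MOWFS-AJS,ranked,3.10,results-text
NB,HAM 10000,FOWFS-AJS,ranked,3.30,results-text
NB,BCN 20000,MOWFS-AJS,ranked,6.27,results-text
NB,BCN 20000,FOWFS-AJS,ranked,6.47,results-text
NB,HAM 10000,FOWFS-AJS,fused,1.00,figure-text
NB,HAM 10000,FOWFS-AJS,ranked,2.00,figure-text
NB,BCN 20000,FOWFS-AJS,fused,3.24,figure-text
NB,BCN 20000,FOWFS-AJS,ranked,6.47,figure-text
MLP,HAM 10000,MOWFS-AJS,ranked,3.30,results-text
MLP,HAM 10000,FOWFS-AJS,ranked,3.58,results-text
MLP,BCN 20000,MOWFS-AJS,ranked,5.49,results-text
MLP,BCN 20000,FOWFS-AJS,ranked,5.57,results-text
MLP,HAM 10000,FOWFS-AJS,fused,1.34,figure-text
MLP,HAM 10000,FOWFS-AJS,ranked,3.51,figure-text
MLP,BCN 20000,FOWFS-AJS,fused,2.99,figure-text
MLP,BCN 20000,FOWFS-AJS,ranked,5.57,figure-text
SVM,HAM 10000,MOWFS-AJS,ranked,3.87,results-text
SVM,HAM 10000,FOWFS-AJS,ranked,5.54,results-text
SVM,BCN 20000,MOWFS-AJS,ranked,4.65,results-text
SVM,BCN 20000,FOWFS-AJS,ranked,6.32,results-text
SVM,HAM 10000,FOWFS-AJS,fused,2.00,figure-text
SVM,HAM 10000,FOWFS-AJS,ranked,5.54,figure-text
SVM,BCN 20000,FOWFS-AJS,fused,1.64,figure-text
SVM,BCN 20000,FOWFS-AJS,ranked,6.35,figure-text
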